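#!/usr/bin/env Rscript
# Optional reproduction of the published strain-level analyses.  Requires
# the original datasets, which are NOT shipped with the package: a directory
# of per-strain ribosomal-proteome FASTA files (one file per strain) and,
# optionally, a directory of per-strain 16s-23s rRNA FASTA files (one
# sequence per file).  Writes trees, classification tables, and the k-mer
# baseline tree to --out-dir.
#
#   Rscript scripts/reproduce_published.R --proteomes <dir> \
#       [--rrna <dir>] [--replicates 100] [--seed 1] [--out-dir results/published]

suppressPackageStartupMessages({
  library(optparse)
  library(nvphylo)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--proteomes", type = "character",
              help = "dir of per-strain ribosomal proteome FASTA files"),
  make_option("--rrna", type = "character",
              help = "dir of per-strain 16s-23s rRNA FASTA files (optional)"),
  make_option("--replicates", type = "integer", default = 100L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", type = "character", dest = "out_dir",
              default = "results/published")
)))
if (is.null(opts$proteomes)) {
  stop("--proteomes is required (the published datasets are not bundled)")
}
dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)

profiles <- load_profiles(opts$proteomes, "PROTEIN")
message("loaded ", length(profiles), " strains: ",
        paste(vapply(profiles, `[[`, character(1), "label"), collapse = ", "))

for (metric in c("euclidean", "manhattan")) {
  st <- bootstrap_support(profiles, opts$replicates, base_metric = metric,
                          seed = opts$seed)
  out <- file.path(opts$out_dir, paste0("proteome_", metric, ".nwk"))
  writeLines(to_newick(st$dendrogram, support = st$support), out)
  message("wrote ", out)
}

report <- evaluate_all(profiles)
print(report)
write_classification(report, file.path(opts$out_dir, "classification"))

km <- kmer_pairwise_matrix(profiles, k = 3)
writeLines(to_newick(single_linkage(km)),
           file.path(opts$out_dir, "kmer3_tree.nwk"))

if (!is.null(opts$rrna)) {
  rprof <- load_profiles(opts$rrna, "DNA")
  dm <- pairwise_matrix(rprof, set_metric = "direct")
  writeLines(to_newick(single_linkage(dm)),
             file.path(opts$out_dir, "rrna_euclidean.nwk"))
}
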