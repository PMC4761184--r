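#!/usr/bin/env Rscript

# Optional, non-gating comparison against externally deposited data.
#
# The full study-scale inputs -- the ~611-molecule core-metabolism set,
# the test-compound structures and the per-endpoint half-effect tables --
# are distributed as an external deposit and are not bundled here. Once a
# user has downloaded them, this script recomputes Ub5/Ub6 for every
# compound against the real metabolite set and the per-endpoint Spearman
# correlations, writing tables that can be set beside the published ones.
# Nothing in the package's tests depends on this script.
#
#   Rscript scripts/compare_deposit.R \
#     --metabolites core_metabolism.smi \        # or .sdf
#     --compounds compounds.sdf \
#     --toxicity endpoints.csv \                 # id, endpoint, log_ec50
#     --out-dir deposit_comparison

suppressMessages({
  library(unbio)
  library(optparse)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--metabolites", type = "character"),
  make_option("--compounds", type = "character"),
  make_option("--toxicity", type = "character", default = NULL),
  make_option("--out-dir", type = "character", default = "deposit_comparison")
)))

read_mols <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) read_sdf_file(path)
  else read_smiles_file(path)
}

dir.create(opt$`out-dir`, showWarnings = FALSE, recursive = TRUE)

metabolites <- read_mols(opt$metabolites)
compounds <- read_mols(opt$compounds)
message(nrow(metabolites), " metabolites, ", nrow(compounds), " compounds")

ub <- ub_table(compounds, metabolites, ns = c(5L, 6L))
utils::write.csv(as.data.frame(ub),
                 file.path(opt$`out-dir`, "ub_scores.csv"),
                 row.names = FALSE)
message("wrote ub_scores.csv (", sum(is.na(ub$note)), " scored, ",
        sum(!is.na(ub$note)), " failed)")

if (!is.null(opt$toxicity)) {
  tox <- utils::read.csv(opt$toxicity, stringsAsFactors = FALSE)
  res <- correlate_endpoints(tox, ub, ns = c(5L, 6L))
  utils::write.csv(as.data.frame(res),
                   file.path(opt$`out-dir`, "correlations.csv"),
                   row.names = FALSE)
  print(as.data.frame(res))
}
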