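# Shared setup for the numbered analysis drivers. Each driver can be run on
# its own with Rscript from the repository root; outputs land in results/.
suppressPackageStartupMessages(library(vowelmarker))

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

SEED_SCREEN <- 101L   # screening cohort
SEED_VALID <- 202L    # clinical validation cohort
SEED_MODEL <- 7L      # SVM cross-validation folds

save_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  manifest <- file.path(RESULTS_DIR, "MANIFEST.txt")
  line <- sprintf("%s  %s  %d rows", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  basename(path), nrow(df))
  cat(line, "\n", file = manifest, append = TRUE, sep = "")
  message("wrote ", path)
  invisible(path)
}
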