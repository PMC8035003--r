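#!/usr/bin/env Rscript
# Optional reproduction of the clinical evaluation on real recordings.
#
# The clinical recordings are not shipped with this package; point --data at
# a directory of single-column CSV pulse recordings (one per subject, see
# read_pulse_series()) plus a labels.csv with columns id,label where label
# is AF, PC or SR.  The sampling rate of the original device is not public,
# so --fs must be supplied unless each file carries an fs= header.
#
# Usage:
#   Rscript scripts/reproduce_clinical.R --data dir/ [--fs N] [--threshold 2.1]

suppressPackageStartupMessages(library(tsaprv))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[[i + 1L]]
}
data_dir <- get_opt("--data")
if (is.null(data_dir) || !dir.exists(data_dir))
  stop("supply --data <directory of recordings + labels.csv>")
fs <- get_opt("--fs"); if (!is.null(fs)) fs <- as.numeric(fs)
thr <- as.numeric(get_opt("--threshold", "2.1"))

labels <- read.csv(file.path(data_dir, "labels.csv"), stringsAsFactors = FALSE)
cohort <- lapply(seq_len(nrow(labels)), function(k) {
  f <- file.path(data_dir, paste0(labels$id[k], ".csv"))
  list(series = read_pulse_series(f, fs = fs, id = labels$id[k]),
       group = labels$label[k])
})

idx <- compute_indexes(cohort, prv_config(af_threshold = thr))
ok <- !is.na(idx$d_e)
idx <- idx[ok, ]
cat(sprintf("%d/%d recordings processed\n", nrow(idx), nrow(labels)))

kp <- kruskal_pairwise(idx$d_e, idx$group)
cat(sprintf("Kruskal-Wallis H = %.3f, p = %.3g\n", kp$H, kp$p_overall))
print(kp$pairs, digits = 4)

roc <- roc_auc(idx$d_e, idx$group == "AF", TRUE)
cat(sprintf("AUC (AF vs rest): %.3f\n", roc$auc))
is_af <- idx$group == "AF"
call_af <- idx$d_e > thr
cat(sprintf("at threshold %.2f: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
            thr, 100 * mean(call_af == is_af),
            100 * mean(call_af[is_af]), 100 * mean(!call_af[!is_af])))
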