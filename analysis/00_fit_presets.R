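#!/usr/bin/env Rscript
# Regenerates the shipped promoter preset registry from the published
# observed cross frequencies. The registry is data, not code: rerunning
# this script after editing inst/extdata/observed_frequencies.tsv
# rewrites inst/extdata/promoter_presets.yaml.

suppressPackageStartupMessages(library(splitdrive))

reg <- fit_all_presets(observed_frequencies())

out <- file.path("inst", "extdata", "promoter_presets.yaml")
if (!dir.exists(dirname(out))) {
  stop("run from the package source root (inst/extdata must exist)")
}
write_presets(reg, out)

cat("wrote", out, "\n")
for (p in names(reg)) {
  m <- reg[[p]]$maternal
  cat(sprintf("%-5s maternal: c_germ_w=%.3f h=%.3f r1_w=%.3f c_y=%.3f | rnp c_emb_w=%.3f\n",
              p, m$c_germ_w, m$h, m$r1_w, m$c_y, reg[[p]]$rnp$c_emb_w))
}
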