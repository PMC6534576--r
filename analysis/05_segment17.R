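#!/usr/bin/env Rscript
# Localization heat map: rate every 17-segment sector positive/negative for
# the infarct and AAR of each phantom heart and sum counts across hearts.

library(cardioclear3d)

dirs <- list.dirs("results/phantoms", recursive = FALSE)
ratings_inf <- list(); ratings_aar <- list()
for (d in dirs) {
  meta <- read_geometry_sidecar(file.path(d, "geometry.yaml"))
  heart <- read_mask(file.path(d, "mask_heart.tif"))
  lumen <- read_mask(file.path(d, "mask_lumen.tif"))
  infarct <- read_mask(file.path(d, "mask_infarct.tif"))
  aar <- read_mask(file.path(d, "mask_aar.tif"))
  slabs <- define_slabs(heart, lumen)
  seg <- assign_segments(heart, lumen, slabs, reference_angle_deg = 0)
  ratings_inf[[d]] <- rate_positivity(seg, infarct)
  ratings_aar[[d]] <- rate_positivity(seg, aar)
}
hm_inf <- aggregate_heatmap(ratings_inf)
hm_aar <- aggregate_heatmap(ratings_aar)
out <- data.frame(segment = hm_inf$segment, infarct_count = hm_inf$count,
                  aar_count = hm_aar$count)
write.csv(out, "results/segment17_heatmap.csv", row.names = FALSE)
print(out)
message("counts are numbers of hearts positive per AHA segment (1-17)")
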