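#!/usr/bin/env Rscript
# Predator-vision conspicuousness of butterfly wing patterns against a
# textured background.
#
# Generates hyperspectral scenes with a spectrally matched butterfly (the
# crypsis control) and with two contrasting reflectances, then computes
# percent luminance change, seven-band granularity spectra with KL
# divergence, and receptor-noise-limited JND maps for trichromatic and
# tetrachromatic observers. Writes results/vision_summary.tsv.

suppressMessages(library(mimicrysim))
dir.create("results", showWarnings = FALSE)
seed <- 20260930L

wl <- seq(360, 660, length.out = 16)
bg <- gaussian_spectrum(wl, 550, 60)
cases <- list(
  matched = bg,
  bluish = gaussian_spectrum(wl, 470, 50),
  bright = bg * 1.5)
observers <- list(trichromat = receptor_model_tri(wl),
                  tetrachromat = receptor_model_tetra(wl))

rows <- list()
for (nm in names(cases)) {
  sc <- generate_scene(scene_spec(butterfly_spectrum = cases[[nm]],
                                  texture_amplitude = 0.2,
                                  seed = seed + match(nm, names(cases))))
  lum <- percent_luminance_change(sc$cube, sc$mask)
  L <- luminance_map(sc$cube)
  kl <- kl_divergence(granularity_spectrum(L, sc$mask),
                      granularity_spectrum(L, !sc$mask))
  for (ob in names(observers)) {
    j <- jnd_map(sc$cube, sc$mask, observers[[ob]])
    rows[[length(rows) + 1]] <- data.frame(
      scene = nm, observer = ob,
      luminance_change_pct = lum$mean, luminance_change_sd = lum$sd,
      granularity_kl = kl, jnd_mean = j$mean, jnd_sd = j$sd,
      jnd_excluded_pixels = j$n_excluded)
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/vision_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE)
message("Interpretation: a butterfly whose reflectance matches the ",
        "background is invisible to the chromatic channel (JND = 0) and ",
        "shows no luminance or pattern contrast; spectral or brightness ",
        "offsets are picked up as JND > 1 and luminance change, for both ",
        "observer models.")
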