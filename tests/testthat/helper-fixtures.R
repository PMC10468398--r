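# shared fixtures: built in code, kept small so the default run stays fast

# the measured 50-nl unit in its monovalent (K+/Cl-) idealization, with
# geometry calibrated to the published ~78 kOhm internal resistance
calibrated_kcl_unit <- function() {
  calibrate_area_factor(power_unit("KCl", volume_nl = 50), 78)
}

# a small, cheap synthetic recording for plumbing tests
small_wave_spec <- function(...) {
  wave_spec(diameter_um = 150, n_somata = 60, speed_um_s = 6,
            duration_s = 30, baseline_frames = 4, ...)
}

# independent bilinear interpolation oracle (scalar, straight from the
# textbook definition)
bilinear_oracle <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  img[y0, x0] * (1 - fx) * (1 - fy) + img[y0, x0 + 1] * fx * (1 - fy) +
    img[y0 + 1, x0] * (1 - fx) * fy + img[y0 + 1, x0 + 1] * fx * fy
}

# textbook pooled-variance one-tailed two-sample t-test oracle
t_test_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tstat, p = stats::pt(tstat, na + nb - 2,
                                        lower.tail = FALSE))
}
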