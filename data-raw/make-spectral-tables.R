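# Builds the plain-text spectral resource files under inst/extdata/sensitivities.
#
# L/M/S cone and melanopic sensitivities are synthetic template curves from the
# Govardovskii et al. (2000) A1 visual-pigment nomogram, evaluated at the corneal
# peak wavelengths used throughout the package (L 565, M 535, S 419, Mel 490 nm),
# tabulated at 1 nm over 380-780 and peak-normalized.  V(lambda) is the CIE 1931
# ybar 10-nm table spline-interpolated to 1 nm.  The CIE 1931 colour-matching
# functions and the CIE daylight components S0/S1/S2 are published 10-nm tables.
#
# Run from the package root:  Rscript data-raw/make-spectral-tables.R

govardovskii_a1 <- function(lambda, lambda_max) {
  # alpha band
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  S_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                    exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band
  lmb <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  S_beta <- 0.26 * exp(-((lambda - lmb) / b)^2)
  s <- S_alpha + S_beta
  s / max(s)
}

out_dir <- "inst/extdata/sensitivities"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

grid1 <- 380:780
write_two_col <- function(file, wl, v, header) {
  con <- file(file.path(out_dir, file), "w")
  writeLines(paste0("# ", header), con)
  writeLines("wavelength_nm\tvalue", con)
  writeLines(sprintf("%d\t%.10g", wl, v), con)
  close(con)
}

peaks <- c(L = 565, M = 535, S = 419, Mel = 490)
for (ch in names(peaks)) {
  v <- govardovskii_a1(grid1, peaks[[ch]])
  fname <- if (ch == "Mel") "synthetic_melanopic_sensitivity_1nm.tsv" else
    sprintf("synthetic_%s_cone_fundamental_1nm.tsv", tolower(ch))
  write_two_col(fname,
                grid1, v,
                sprintf(paste0("synthetic %s sensitivity: Govardovskii A1 nomogram, ",
                               "corneal peak %d nm, peak-normalized"),
                        ch, peaks[[ch]]))
}

# CIE 1931 2-deg colour-matching functions, 10 nm, 400-700 nm
cmf <- matrix(c(
  400, 0.0143, 0.0004, 0.0679,
  410, 0.0435, 0.0012, 0.2074,
  420, 0.1344, 0.0040, 0.6456,
  430, 0.2839, 0.0116, 1.3856,
  440, 0.3483, 0.0230, 1.7471,
  450, 0.3362, 0.0380, 1.7721,
  460, 0.2908, 0.0600, 1.6692,
  470, 0.1954, 0.0910, 1.2876,
  480, 0.0956, 0.1390, 0.8130,
  490, 0.0320, 0.2080, 0.4652,
  500, 0.0049, 0.3230, 0.2720,
  510, 0.0093, 0.5030, 0.1582,
  520, 0.0633, 0.7100, 0.0782,
  530, 0.1655, 0.8620, 0.0422,
  540, 0.2904, 0.9540, 0.0203,
  550, 0.4334, 0.9950, 0.0087,
  560, 0.5945, 0.9950, 0.0039,
  570, 0.7621, 0.9520, 0.0021,
  580, 0.9163, 0.8700, 0.0017,
  590, 1.0263, 0.7570, 0.0011,
  600, 1.0622, 0.6310, 0.0008,
  610, 1.0026, 0.5030, 0.0003,
  620, 0.8544, 0.3810, 0.0002,
  630, 0.6424, 0.2650, 0.0000,
  640, 0.4479, 0.1750, 0.0000,
  650, 0.2835, 0.1070, 0.0000,
  660, 0.1649, 0.0610, 0.0000,
  670, 0.0874, 0.0320, 0.0000,
  680, 0.0468, 0.0170, 0.0000,
  690, 0.0227, 0.0082, 0.0000,
  700, 0.0114, 0.0041, 0.0000), ncol = 4, byrow = TRUE)
con <- file(file.path(out_dir, "cie1931_cmf_10nm.tsv"), "w")
writeLines("# CIE 1931 2-deg colour-matching functions, 10 nm tabulation", con)
writeLines("wavelength_nm\txbar\tybar\tzbar", con)
writeLines(sprintf("%d\t%.4f\t%.4f\t%.4f", cmf[, 1], cmf[, 2], cmf[, 3], cmf[, 4]), con)
close(con)

# V(lambda) = ybar, spline to 1 nm over 400-700, clamped non-negative, renormalized
grid1v <- 400:700
v1 <- pmax(0, spline(cmf[, 1], cmf[, 3], xout = grid1v, method = "natural")$y)
write_two_col("vlambda_1nm.tsv", grid1v, v1 / max(v1),
              "V(lambda): CIE 1931 ybar 10-nm table spline-interpolated to 1 nm, peak-normalized")

# CIE daylight components S0/S1/S2, 10 nm, 400-700 nm
sd <- matrix(c(
  400,  94.80, 43.40, -1.10,
  410, 104.80, 46.30, -0.50,
  420, 105.90, 43.90, -0.70,
  430,  96.80, 37.10, -1.20,
  440, 113.90, 36.70, -2.60,
  450, 125.60, 35.90, -2.90,
  460, 125.50, 32.60, -2.80,
  470, 121.30, 27.90, -2.60,
  480, 121.30, 24.30, -2.60,
  490, 113.50, 20.10, -1.80,
  500, 113.10, 16.20, -1.50,
  510, 110.80, 13.20, -1.30,
  520, 106.50,  8.60, -1.20,
  530, 108.80,  6.10, -1.00,
  540, 105.30,  4.20, -0.50,
  550, 104.40,  1.90, -0.30,
  560, 100.00,  0.00,  0.00,
  570,  96.00, -1.60,  0.20,
  580,  95.10, -3.50,  0.50,
  590,  89.10, -3.50,  2.10,
  600,  90.50, -5.80,  3.20,
  610,  90.30, -7.20,  4.10,
  620,  88.40, -8.60,  4.70,
  630,  84.00, -9.50,  5.10,
  640,  85.10,-10.90,  6.70,
  650,  81.90,-10.70,  7.30,
  660,  82.60,-12.00,  8.60,
  670,  84.90,-14.00,  9.80,
  680,  81.30,-13.60, 10.20,
  690,  71.90,-12.00,  8.30,
  700,  74.30,-13.30,  9.80), ncol = 4, byrow = TRUE)
con <- file(file.path(out_dir, "cie_daylight_components_10nm.tsv"), "w")
writeLines("# CIE daylight components S0, S1, S2, 10 nm tabulation", con)
writeLines("wavelength_nm\tS0\tS1\tS2", con)
writeLines(sprintf("%d\t%.2f\t%.2f\t%.2f", sd[, 1], sd[, 2], sd[, 3], sd[, 4]), con)
close(con)

cat("wrote", length(list.files(out_dir)), "files to", out_dir, "\n")
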