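# minimal two-channel plate built in code: one blank, one sample well
tiny_plate <- function(t, od_sample, fluo_sample, bg_od = 0.09, bg_fl = 30) {
  plate <- rbind(
    data.frame(time_min = t, well = "B1", channel = "OD600", value = bg_od),
    data.frame(time_min = t, well = "B1", channel = "RFP", value = bg_fl),
    data.frame(time_min = t, well = "S1", channel = "OD600",
               value = od_sample + bg_od),
    data.frame(time_min = t, well = "S1", channel = "RFP",
               value = fluo_sample + bg_fl))
  wellmap <- data.frame(
    well = c("B1", "S1"), strain = c("none", "x"),
    role = c("blank_medium", "sample"), inducer = "none", conc_nM = 0)
  list(plate = plate, wellmap = wellmap)
}

test_that("blank subtraction removes a known additive background", {
  t <- seq(0, 200, 5)
  od <- 0.01 * exp(0.006 * t)
  fl <- cumsum(c(0, diff(t)) * od) * 5
  px <- tiny_plate(t, od, fl)
  corr <- subtract_background(px$plate, px$wellmap)
  s_od <- corr$value[corr$well == "S1" & corr$channel == "OD600"]
  s_fl <- corr$value[corr$well == "S1" & corr$channel == "RFP"]
  b_od <- corr$value[corr$well == "B1" & corr$channel == "OD600"]
  expect_equal(s_od, od, tolerance = 1e-12)
  expect_equal(s_fl, fl, tolerance = 1e-12)
  expect_equal(b_od, rep(0, length(t)))          # blank is its own background
  expect_error(subtract_background(px$plate, within(px$wellmap,
                                                    role <- "sample")),
               "blank_medium")
})

test_that("a sample identical to the autofluorescence control corrects to zero", {
  t <- seq(0, 400, 5)
  od <- 0.01 * exp(0.005 * t)
  af <- 50 * od                                  # autofluorescence ~ biomass
  plate <- rbind(
    data.frame(time_min = t, well = "B1", channel = "OD600", value = 0.09),
    data.frame(time_min = t, well = "B1", channel = "GFP", value = 20),
    data.frame(time_min = t, well = "C1", channel = "OD600", value = od + 0.09),
    data.frame(time_min = t, well = "C1", channel = "GFP", value = af + 20),
    data.frame(time_min = t, well = "S1", channel = "OD600", value = od + 0.09),
    data.frame(time_min = t, well = "S1", channel = "GFP", value = af + 20))
  wellmap <- data.frame(
    well = c("B1", "C1", "S1"), strain = c("none", "ctrl", "ctrl"),
    role = c("blank_medium", "autofluorescence_control", "sample"),
    inducer = "none", conc_nM = 0)
  corr <- subtract_background(plate, wellmap)
  s <- corr$value[corr$well == "S1" & corr$channel == "GFP"]
  expect_lt(max(abs(s)), 1e-6 * max(af))
})

test_that("exponential window spans the band and excludes the plateau", {
  t <- seq(0, 900, 5)
  # pure exponential truncated below saturation: window covers the band
  od <- 0.01 * exp(0.6 * t / 60)
  od <- pmin(od, 0.7)
  w <- exponential_window(t, od)
  expect_gte(min(od[w$idx]), 0.05 * max(od))
  expect_lte(max(od[w$idx]), 0.5 * max(od))
  expect_gte(w$r_squared, 0.99)
  # plateau points after saturation do not change the selected window
  od2 <- c(od, rep(max(od), 30))
  t2 <- seq(0, by = 5, length.out = length(od2))
  w2 <- exponential_window(t2, od2)
  expect_equal(w2$start, w$start)
  expect_equal(w2$end, w$end)
  # flat series: no growth, explicit failure
  expect_error(exponential_window(t, rep(0.3, length(t))), "no exponential")
})

test_that("growth rate is exact on an exponential and robust to mild noise", {
  t <- seq(0, 600, 5)
  od <- 0.01 * exp(0.6931 * t / 60)              # doubling time 1 h
  w <- exponential_window(t, od)
  gr <- growth_rate(t, od, w)
  expect_equal(gr$mu, 0.6931, tolerance = 1e-9)
  expect_equal(gr$r_squared, 1, tolerance = 1e-9)
  set.seed(5)
  odn <- od * exp(rnorm(length(od), 0, sqrt(log(1 + 0.02^2))))
  grn <- growth_rate(t, odn, exponential_window(t, odn))
  expect_lt(abs(grn$mu - 0.6931) / 0.6931, 0.05)
  expect_error(growth_rate(t, od, list(idx = 1:2)), ">= 3")
  odneg <- od; odneg[w$idx[2]] <- -1e-6
  expect_error(growth_rate(t, odneg, w), "non-positive OD")
})

test_that("synthesis rate recovers constant per-cell production", {
  t <- seq(0, 100, 5)
  # linear accumulation at constant biomass: S = slope / OD everywhere
  S <- synthesis_rate(t, fluo = 3 * t, od = rep(0.2, length(t)))
  expect_equal(S, rep(15, length(t)))
  # constant fluorescence: no synthesis
  expect_equal(synthesis_rate(t, rep(7, length(t)), rep(0.2, length(t))),
               rep(0, length(t)))
  # OD below the floor is masked
  od <- c(rep(0.001, 3), rep(0.2, length(t) - 3))
  S <- synthesis_rate(t, 3 * t, od)
  expect_true(all(is.na(S[1:3])) && all(!is.na(S[-(1:3)])))
  expect_error(synthesis_rate(t, 3 * t, rep(1e-5, length(t))), "masked")
})

test_that("s_cell is a channel-matched ratio", {
  expect_equal(s_cell(10, 10), 1)
  expect_equal(s_cell(0, 10), 0)
  expect_equal(s_cell(25, 10), 2.5)
  expect_error(s_cell(1, 0), "> 0")
  expect_error(s_cell(1, 1, channel = "RFP", ref_channel = "GFP"),
               "mismatch")
})

test_that("process_plate reduces a synthetic plate to truthful kinetics", {
  tr <- plate_truth(noise_cv = 0, seed = 3)
  gp <- generate_plate(tr)
  kin <- process_plate(gp$plate, gp$wellmap)
  expect_s3_class(kin, "plate_kinetics")
  m <- merge(as.data.frame(kin),
             tr$wells[c("well", "mu_true", "s_true_RFP")], by = "well")
  expect_true(all(abs(m$mu_per_h - m$mu_true) / m$mu_true < 0.01))
  samp <- m[m$role == "sample", ]
  expect_true(all(abs(samp$S_cell_RFP - samp$s_true_RFP / 20) /
                    (samp$s_true_RFP / 20) < 0.01))
  # scale invariance: rescaling all fluorescence leaves S_cell unchanged
  plate2 <- gp$plate
  rfp <- plate2$channel == "RFP"
  plate2$value[rfp] <- plate2$value[rfp] * 37
  kin2 <- process_plate(plate2, gp$wellmap)
  expect_equal(kin2$S_cell_RFP, kin$S_cell_RFP, tolerance = 1e-9)
})

test_that("replicate aggregation returns mean and sem per condition", {
  kin <- data.frame(strain = c("a", "a", "a", "b"), inducer = "HSL",
                    conc_nM = c(1, 1, 1, 1), mu_per_h = c(0.5, 0.6, 0.7, 0.4),
                    S_cell_RFP = c(1, 2, 3, 5))
  agg <- aggregate_replicates(kin)
  a <- agg[agg$strain == "a", ]
  expect_equal(a$n_replicates, 3)
  expect_equal(a$S_cell_RFP_mean, 2)
  expect_equal(a$S_cell_RFP_sem, sd(1:3) / sqrt(3))
})
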