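test_that("phase schedule encodes the 14-phase design", {
  sched <- phase_schedule()
  expect_equal(sched$phase, LETTERS[1:14])
  heat <- sched$minutes[sched$condition == "heat"]
  rec <- sched$minutes[sched$condition == "recovery"]
  expect_true(all(diff(heat) > 0))
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, c(15, 30, 60, 90, 120, 240, 480))
})

test_that("phase extremes match the published table and a brute-force scan", {
  tab <- load_dab_table()
  top <- phase_extreme(tab, "E", "max")
  expect_equal(top, list(species = "Csin", phase = "E", value = 116.6))
  bottom <- phase_extreme(tab, "N", "min")
  expect_equal(bottom, list(species = "Tj", phase = "N", value = 38.9))
  # brute-force scan over a random phase subset
  phases <- c("C", "G", "J")
  sub <- tab[tab$phase %in% phases, ]
  expect_equal(phase_extreme(tab, phases, "max")$value, max(sub$mean))
  expect_equal(phase_extreme(tab, phases, "min")$value, min(sub$mean))
  # degenerate single-cell input
  one <- tab[tab$species == "Tj" & tab$phase == "A", ]
  expect_equal(phase_extreme(one, "A", "max")$value, 0.3)
  expect_error(phase_extreme(tab, character(0)), "non-empty")
})

test_that("clearance time implements the sustained-threshold rule", {
  series <- data.frame(species = "x", phase = LETTERS[1:14],
                       mean = c(5, 20, 50, 60, 70, 80, 90,
                                5, 5, 5, 5, 5, 5, 5),
                       sd = rep(0, 14))
  expect_equal(clearance_time(series)$phase, "H")
  # monotonically rising recovery never clears
  series$mean[8:14] <- seq(60, 120, length.out = 7)
  expect_true(is.na(clearance_time(series)$phase))
  # a transient rise above threshold postpones clearance (sustained rule)
  series$mean[8:14] <- c(30, 4, 40, 4, 4, 4, 4)
  expect_equal(clearance_time(series)$phase, "K")
  # margin uses the baseline SD
  series$sd[1] <- 10
  series$mean[8:14] <- c(24, 24, 24, 24, 24, 24, 24)
  expect_equal(clearance_time(series, margin = 2)$phase, "H")  # thr = 25
  expect_true(is.na(clearance_time(series, margin = 1)$phase)) # thr = 15
})

test_that("clearance is monotone under uniform lowering of recovery values", {
  g <- gen_dab_series(seed = 3, profile = "tolerant", clearance_phase = "L",
                      replicate_noise_sd = 0)
  s <- g$series
  base <- clearance_time(s)
  lowered <- s
  rec_idx <- s$phase %in% LETTERS[8:14]
  lowered$mean[rec_idx] <- lowered$mean[rec_idx] - 10
  low <- clearance_time(lowered)
  phase_rank <- function(p) if (is.na(p)) Inf else match(p, LETTERS[8:14])
  expect_lte(phase_rank(low$phase), phase_rank(base$phase))
})

test_that("net recovery subtracts the endpoint from the recovery start", {
  tab <- load_dab_table()
  expect_equal(net_recovery(tab[tab$species == "Tj", ]), 88.2 - 38.9)
  expect_equal(net_recovery(tab[tab$species == "Aj", ]), 49.1 - 70.7)
  flat <- data.frame(phase = LETTERS[1:14], mean = rep(7, 14))
  expect_equal(net_recovery(flat), 0)
})

test_that("species ranking keys on endpoint N with documented tie-breaks", {
  tab <- load_dab_table()
  rk <- rank_species(tab)
  expect_equal(rk$species[1], "Tj")
  expect_equal(rk$species[nrow(rk)], "Qa")
  # scale invariance
  scaled <- tab
  scaled$mean <- scaled$mean * 3.5
  expect_equal(rank_species(scaled)$species, rk$species)
  # identical series tie-break by species code
  dup <- tab[tab$species == "Tj", ]
  dup2 <- dup; dup2$species <- "Aa"
  both <- rbind(dup, dup2)
  expect_equal(rank_species(both)$species, c("Aa", "Tj"))
  # incomplete series excluded with a warning
  broken <- rbind(tab, data.frame(species = "Zz", phase = "A", mean = 1,
                                  sd = 0, letter = ""))
  expect_warning(rk2 <- rank_species(broken), "Zz")
  expect_false("Zz" %in% rk2$species)
})

test_that("profile clustering separates planted kinetic regimes", {
  tol1 <- gen_dab_series(seed = 1, profile = "tolerant",
                         clearance_phase = "M", species = "t1")$series
  tol2 <- gen_dab_series(seed = 2, profile = "tolerant",
                         clearance_phase = "L", species = "t2")$series
  sen1 <- gen_dab_series(seed = 3, profile = "sensitive",
                         species = "s1")$series
  sen2 <- gen_dab_series(seed = 4, profile = "sensitive",
                         species = "s2")$series
  tab <- rbind(tol1, tol2, sen1, sen2)
  cl <- cluster_profiles(tab, k = 2)
  expect_equal(cl[["t1"]], cl[["t2"]])
  expect_equal(cl[["s1"]], cl[["s2"]])
  expect_true(cl[["t1"]] != cl[["s1"]])
  # degenerate k = number of species: singletons
  expect_equal(sort(unname(cluster_profiles(tab, k = 4))), 1:4)
  expect_error(cluster_profiles(tab, k = 5), "between")
})

test_that("radar export normalizes to [0,1] with tolerant orientation", {
  tab <- load_dab_table()
  # none of the published series clears, so the clearance axis is constant
  # across the fixture and is dropped with a warning
  expect_warning(rad <- radar_export(tab), "constant")
  axes <- setdiff(names(rad), "species")
  expect_true(length(axes) >= 3)
  for (ax in axes) {
    expect_gte(min(rad[[ax]]), 0)
    expect_lte(max(rad[[ax]]), 1)
  }
  # species with the lowest endpoint scores highest on that axis
  expect_equal(rad$species[which.max(rad$low_endpoint)], "Tj")
  # two species: each retained axis is exactly {0, 1}
  two <- tab[tab$species %in% c("Tj", "Aj"), ]
  rad2 <- suppressWarnings(radar_export(two))
  for (ax in setdiff(names(rad2), "species"))
    expect_setequal(rad2[[ax]], c(0, 1))
  # constant axes are dropped with a warning
  dup <- tab[tab$species == "Tj", ]
  dup2 <- dup; dup2$species <- "Tk"
  w <- capture_warnings(rad3 <- radar_export(rbind(dup, dup2)))
  expect_true(length(w) > 0 && all(grepl("constant", w)))
  expect_equal(names(rad3), "species")
})

test_that("recovery summaries classify cleared, declining and persistent", {
  tab <- load_dab_table()
  tj <- recovery_summary(tab, "Tj")
  expect_equal(tj$recovery_class, "declining")  # declines but stays high
  aj <- recovery_summary(tab, "Aj")
  expect_equal(aj$recovery_class, "persistent")
  g <- gen_dab_series(seed = 5, profile = "tolerant", clearance_phase = "N")
  expect_equal(recovery_summary(g$series, "syn")$recovery_class, "cleared")
})
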