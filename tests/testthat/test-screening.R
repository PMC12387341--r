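test_that("standardization yields exact z-scores with sample SD", {
  pairs <- data.frame(species = c("a", "b"), rwc = c(60, 80), eli = c(2, 4))
  std <- standardize(pairs)
  expect_equal(std$z_rwc, c(-1, 1) / sqrt(2))
  expect_equal(std$z_eli, c(-1, 1) / sqrt(2))
  # cohort-level normalization invariant
  set.seed(4)
  pairs <- data.frame(species = sprintf("s%d", 1:12),
                      rwc = runif(12, 30, 90), eli = runif(12, 0.5, 9))
  std <- standardize(pairs)
  expect_equal(mean(std$z_rwc), 0, tolerance = 1e-9)
  expect_equal(sd(std$z_rwc), 1, tolerance = 1e-9)
  expect_equal(mean(std$z_eli), 0, tolerance = 1e-9)
  expect_equal(sd(std$z_eli), 1, tolerance = 1e-9)
  expect_equal(std$species, pairs$species)  # order preserved
  # degenerate cohorts are refused
  expect_error(standardize(data.frame(species = c("a", "b"), rwc = c(1, 1),
                                      eli = c(2, 3))), "degenerate")
  expect_error(standardize(pairs[1, ]), "at least 2")
})

test_that("standardization is invariant under positive affine rescaling", {
  set.seed(5)
  pairs <- data.frame(species = sprintf("s%d", 1:10),
                      rwc = runif(10, 30, 90), eli = runif(10, 0.5, 9))
  std <- standardize(pairs)
  resc <- data.frame(species = pairs$species,
                     rwc = 3.7 * pairs$rwc + 12, eli = 0.2 * pairs$eli + 1)
  expect_equal(standardize(resc), std, tolerance = 1e-12)
})

test_that("quadrants follow the sign conventions, zeros are boundary", {
  expect_equal(quadrant(1.2, -0.8), "II")
  expect_equal(quadrant(-1.5, 1.9), "IV")
  expect_equal(quadrant(0.5, 0.5), "I")
  expect_equal(quadrant(-0.5, -0.5), "III")
  expect_equal(quadrant(0, 1), "boundary")
  expect_equal(quadrant(1, 0), "boundary")
})

test_that("printed pre-screening cohort reproduces the published quadrants", {
  std <- standardize(prescreen_pairs())
  quads <- setNames(quadrant(std$z_rwc, std$z_eli), std$species)
  expect_equal(unname(quads[c("Co", "Qm", "Qg")]), rep("II", 3))
  expect_equal(unname(quads["Aj"]), "IV")
})

test_that("candidate selection uses distance to the reference centroid", {
  std <- data.frame(species = c("r1", "r2", "near", "far"),
                    z_rwc = c(1, 1, 1, -2), z_eli = c(-1, -0.5, -0.75, 2))
  # centroid of r1, r2 = (1, -0.75); "near" is at distance 0
  sel <- select_candidates(std, c("r1", "r2"), radius = 1)
  expect_equal(sel$species, "near")
  expect_equal(sel$distance, 0)
  # species beyond the radius excluded
  expect_false("far" %in% sel$species)
  # k-nearest mode ignores the radius
  sel_k <- select_candidates(std, c("r1", "r2"), k = 2)
  expect_equal(sel_k$species, c("near", "far"))
  expect_error(select_candidates(std, character(0)), "non-empty")
  expect_error(select_candidates(std, "absent"), "not in cohort")
})

test_that("classification applies the full rule set", {
  res <- classify(prescreen_pairs(), references = c("Co", "Qm", "Qg"))
  expect_s3_class(res, "tolerance_screen")
  expect_equal(res$class[res$species == "Aj"], "sensitive")
  expect_equal(res$class[res$species %in% c("Co", "Qm", "Qg")],
               rep("tolerant", 3))
  # references stay tolerant regardless of distance
  res2 <- classify(prescreen_pairs(), references = c("Co", "Aj"))
  expect_equal(res2$class[res2$species == "Aj"], "tolerant")
  # boundary points are never binned into a class
  pairs <- data.frame(species = c("a", "b", "c"),
                      rwc = c(50, 60, 70), eli = c(3, 4, 5))
  res3 <- classify(pairs, references = "a")
  expect_equal(res3$class[res3$species == "b"], "unclassified")
  expect_equal(res3$quadrant[res3$species == "b"], "boundary")
})

test_that("classification is permutation-equivariant in cohort order", {
  set.seed(6)
  ch <- gen_cohort(seed = 20, n_species = 14, separation = 3)
  refs <- ch$pairs$species[which(ch$labels == "tolerant")[1:3]]
  res <- classify(ch$pairs, references = refs, radius = 2.5)
  perm <- sample(nrow(ch$pairs))
  res_p <- classify(ch$pairs[perm, ], references = refs, radius = 2.5)
  reord <- res_p[match(res$species, res_p$species), ]
  expect_equal(reord$class, res$class)
  expect_equal(reord$z_rwc, res$z_rwc)
})

test_that("stage report labels stages and flags missing data", {
  rwc_sum <- data.frame(species = c("Qg", "Aj"), rwc = c(75, 35))
  eli_sum <- data.frame(species = c("Qg", "Aj"), eli = c(2, 8))
  rec_sum <- data.frame(species = "Qg", recovery_class = "cleared")
  rep_tab <- stage_report(rwc_sum, eli_sum, rec_sum)
  qg <- rep_tab[rep_tab$species == "Qg", ]
  expect_equal(qg$label[qg$stage == "drought"],
               "high water retention (stable RWC)")
  expect_equal(qg$label[qg$stage == "recovery"],
               "ROS scavenging, tissue restoration")
  aj <- rep_tab[rep_tab$species == "Aj", ]
  expect_equal(aj$label[aj$stage == "heat"], "high electrolyte leakage")
  expect_true(aj$incomplete[aj$stage == "recovery"])
  # thresholds act monotonically: raising rwc_min can only flip
  # water-retaining labels to declining, never the reverse
  labels_at <- function(th) {
    r <- stage_report(rwc_sum, eli_sum, rec_sum, rwc_min = th)
    r$label[r$stage == "drought"]
  }
  lab_seq <- lapply(c(20, 40, 60, 80), labels_at)
  retained <- vapply(lab_seq, function(l)
    sum(l == "high water retention (stable RWC)"), numeric(1))
  expect_true(all(diff(retained) <= 0))
})
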