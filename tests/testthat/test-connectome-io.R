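test_that("region table parsing validates ids, columns and values", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(id = 1:4, name = paste0("r", 1:4),
                    hemisphere = c("L", "L", "R", "R"),
                    x = c(-10, -20, 10, 20), y = 0, z = 0,
                    module = "m1", cortical = TRUE)
  utils::write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- read_region_table(tf)
  expect_equal(nrow(rt), 4)
  expect_equal(rt$name, paste0("r", 1:4))

  tab2 <- tab; tab2$id[2] <- 3
  utils::write.table(tab2, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_region_table(tf), "duplicate region id")

  utils::write.table(tab[-which(names(tab) == "module")], tf, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_region_table(tf), "module")
})

test_that("connectome construction enforces symmetry, sign and diagonal", {
  W <- matrix(c(0, 1, 2, 1, 0, 0, 2, 0, 0), 3, 3)
  cn <- connectome(W)
  expect_equal(sum(cn$weights[upper.tri(cn$weights)] > 0), 2)

  W2 <- W; W2[1, 2] <- 1 + 1e-12  # rounding-level asymmetry is symmetrised
  expect_silent(cn2 <- connectome(W2))
  expect_equal(cn2$weights, t(cn2$weights))

  W3 <- W; W3[1, 2] <- 1.5        # genuine asymmetry is data corruption
  expect_error(connectome(W3), "asymmetry")
  expect_error(connectome(-W), "nonnegative")
  expect_error(connectome(W[, 1:2]), "square")
})

test_that("connectome write/read round-trips exactly and checks shape", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  set.seed(1)
  W <- random_weighted_graph(5)
  cn <- connectome(W, lengths = (W > 0) * 25.3)
  write_connectome(cn, tf)
  back <- read_connectome(tf, 5)
  expect_equal(back$weights, cn$weights, tolerance = 1e-12)
  expect_equal(back$lengths, cn$lengths, tolerance = 1e-12)
  expect_error(read_connectome(tf, 4), "expected 4x4")
})

test_that("cohort loading sorts, rejects out-of-range ages, is order-independent", {
  dir <- withr::local_tempdir()
  conns <- lapply(1:5, function(i) connectome(k3()))
  mp <- write_cohort_fixture(dir, NULL, conns)
  regions <- data.frame(id = 1:3, name = c("a", "b", "c"),
                        hemisphere = c("L", "L", "R"), x = c(-1, -2, 1),
                        y = 0, z = 0, module = "m1", cortical = TRUE)
  coh <- quiet_load_cohort(mp, regions)
  expect_s3_class(coh, "cohort")
  expect_equal(nrow(coh$scans), 5)
  expect_equal(as.integer(sort(table(coh$scans$subject))), c(1L, 2L, 2L))

  # age outside bounds -> rejected with warning
  man <- utils::read.csv(mp)
  man$age[1] <- 25
  utils::write.csv(man, mp, row.names = FALSE)
  expect_warning(coh2 <- quiet_load_cohort(mp, regions), "rejected")
  expect_equal(nrow(coh2$scans), 4)

  # shuffled manifest rows give the same cohort after canonical sorting
  man2 <- man[sample(nrow(man)), ]
  mp2 <- file.path(dir, "manifest2.csv")
  utils::write.csv(man2, mp2, row.names = FALSE)
  coh3 <- suppressWarnings(quiet_load_cohort(mp2, regions))
  expect_equal(coh3$scans, coh2$scans)

  # empty cohort is an error
  utils::write.csv(man[0, ], mp, row.names = FALSE)
  expect_error(quiet_load_cohort(mp, regions), "empty cohort")
})

test_that("prevalence threshold keeps edges at >= 75% presence, mean over all scans", {
  # edge (1,2) present in 3/4 scans, edge (2,3) in 2/4
  mk <- function(w12, w23) connectome(p3(c(w12, w23)))
  coh <- as_cohort(data.frame(subject = sprintf("s%d", 1:4), wave = 1,
                              age = 8:11, sex = "F", tbv = 1, centre = "c1"),
                   list(mk(2, 1), mk(4, 1), mk(6, 0), mk(0, 0)))
  g <- group_average_network(coh, prevalence = 0.75)
  expect_equal(g$weights[1, 2], mean(c(2, 4, 6, 0)))  # kept at exactly 3/4
  expect_equal(g$weights[2, 3], 0)                    # zeroed at 2/4
  expect_error(group_average_network(coh, prevalence = 0), "prevalence")

  # single-scan cohort: group support equals the scan support
  coh1 <- as_cohort(coh$scans[1, ], list(mk(2, 1)))
  g1 <- group_average_network(coh1)
  expect_equal(g1$weights, mk(2, 1)$weights)

  # raising prevalence never adds edges
  g_lo <- group_average_network(coh, 0.5)
  expect_true(all(which(g$weights > 0) %in% which(g_lo$weights > 0)))
})
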