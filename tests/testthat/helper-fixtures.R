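# small deterministic fixtures shared across test files

k3 <- function(w = c(1, 1, 1)) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w[1]
  W[2, 3] <- W[3, 2] <- w[2]
  W[1, 3] <- W[3, 1] <- w[3]
  W
}

p3 <- function(w = c(1, 1)) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w[1]
  W[2, 3] <- W[3, 2] <- w[2]
  W
}

star5 <- function() {
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 1
  W
}

write_cohort_fixture <- function(dir, regions, conns, ages = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(conns)
  if (is.null(ages)) ages <- seq(7, 12, length.out = n)
  paths <- character(n)
  for (k in seq_len(n)) {
    paths[k] <- file.path(dir, sprintf("scan%02d.tsv", k))
    write_connectome(conns[[k]], paths[k])
  }
  man <- data.frame(subject = sprintf("s%02d", ceiling(seq_len(n) / 2)),
                    wave = rep_len(1:2, n), age = ages,
                    sex = rep_len(c("F", "M"), n), tbv = 1.4e6 + seq_len(n) * 1e3,
                    centre = "c1", matrix_path = basename(paths))
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  mp
}

quiet_load_cohort <- function(...) suppressMessages(load_cohort(...))

# lazily cached shared synthetic objects (kept small)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

test_regions <- function() cached("regions90", make_regions(90, seed = 42))

cortical_dist <- function(regions) {
  as.matrix(stats::dist(as.matrix(regions[regions$cortical, c("x", "y", "z")])))
}
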