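toy_fossils <- function() {
  data.frame(
    genus = c("Hipparion", "Hipparion", "Gomphotherium", "Ochotona"),
    family = c("Equidae", "Equidae", "Gomphotheriidae", "Ochotonidae"),
    lon = c(85, 85, 100.04, 100.08),
    lat = c(43, 43, 30.01, 30.06),
    min_age = c(5.3, 5.3, 15, 2),
    max_age = c(11.6, 11.6, 20, 4),
    stringsAsFactors = FALSE)
}

test_that("deduplication removes exact duplicates only", {
  rec <- toy_fossils()
  expect_message(out <- dedup_occurrences(rec), "1 duplicate")
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_duplicates"), 1L)

  # same genus at a different locality is kept
  rec2 <- rec[c(1, 3), ]
  out2 <- dedup_occurrences(rec2)
  expect_equal(nrow(out2), 2L)

  rec3 <- rbind(rec, rec[3:4, ], rec[4, ])  # extra duplicate pairs
  out3 <- suppressMessages(dedup_occurrences(rec3))
  expect_equal(nrow(out3), 3L)
})

test_that("locality merging bins coordinates on a fixed grid", {
  rec <- data.frame(genus = c("A", "B", "C"),
                    lon = c(90.02, 90.07, 90.02),
                    lat = c(30.05, 30.08, 30.15),
                    min_age = 1, max_age = 2)
  out <- merge_localities(rec)
  expect_equal(out$locality[1], out$locality[2])   # same 0.1-deg bin
  expect_false(out$locality[1] == out$locality[3]) # lat bin differs
  expect_equal(out$loc_lon[1], 90.05)
  expect_equal(out$loc_lat[1], 30.05)

  # single record just gains a locality id
  one <- merge_localities(rec[1, ])
  expect_equal(nrow(one), 1L)
  expect_true("locality" %in% names(one))

  # coarser bins never increase the number of distinct localities
  set.seed(81)
  many <- data.frame(genus = "G", lon = runif(50, 0, 3),
                     lat = runif(50, 0, 3), min_age = 1, max_age = 2)
  n_loc <- vapply(c(0.05, 0.1, 0.5, 1),
                  function(tol)
                    length(unique(merge_localities(many, tol)$locality)),
                  numeric(1))
  expect_true(all(diff(n_loc) <= 0))
})

test_that("interval assignment uses mean age with inclusive young bounds", {
  rec <- data.frame(genus = c("a", "b", "c", "d"),
                    lon = 0, lat = 0,
                    min_age = c(40, 23.0, 56, 0.001),
                    max_age = c(50, 23.0, 64, 0.001))
  out <- suppressMessages(assign_interval(rec))
  expect_equal(out$mean_age, c(45, 23, 60, 0.001))
  expect_equal(out$interval[1], "Eocene")
  expect_equal(out$interval[2], "Oligocene")   # young bound inclusive
  expect_true(is.na(out$interval[3]))          # older than all intervals
  expect_true(is.na(out$interval[4]))          # younger than all intervals
  expect_equal(attr(out, "n_unassigned"), 2L)

  bad <- cenozoic_intervals()
  bad$young[1] <- 60
  expect_error(assign_interval(rec, bad), "old > young")
  over <- cenozoic_intervals()
  over$young[1] <- 30
  expect_error(assign_interval(rec, over), "overlap")
})

test_that("region-genus incidence matches hand tabulation", {
  lookup <- make_region_lookup(
    data.frame(lon = c(0, 10, 20), lat = c(0, 0, 0)),
    c("West", "Mid", "East"))
  rec <- data.frame(
    genus = c("g1", "g2", "g1", "g3", "g3", "g2", "g1", "g1"),
    lon = c(0, 0, 10, 10, 20, 20, 20, 0),
    lat = 0,
    min_age = 40, max_age = 50)
  rec <- suppressMessages(assign_interval(rec))
  m <- region_genus_incidence(rec, lookup, "Eocene")
  expect_equal(sort(rownames(m)), c("East", "Mid", "West"))
  expect_equal(m["West", ], c(g1 = 1L, g2 = 1L, g3 = 0L))
  expect_equal(m["Mid", ], c(g1 = 1L, g2 = 0L, g3 = 1L))
  expect_equal(m["East", ], c(g1 = 1L, g2 = 1L, g3 = 1L))
  expect_equal(sum(m["East", ]), 3L)
  expect_equal(unname(colSums(m)["g1"]), 3)

  expect_error(region_genus_incidence(rec, lookup, "Oligocene"),
               "no records")
  far <- rec
  far$lon[1] <- 55
  expect_error(region_genus_incidence(far, lookup, "Eocene"),
               "outside the region lookup")
})

test_that("cleaning counts partition the raw input rows", {
  f <- write_lines(c(
    "genus,lon,lat,min_age,max_age",
    "Hipparion,85,43,5.3,11.6",
    "Hipparion,85,43,5.3,11.6",     # duplicate
    "indet.,85,43,5.3,11.6",        # indeterminate
    "Ochotona,85,43,100,120",       # mean age outside intervals
    "Gomphotherium,100,30,15,20"), ".csv")
  rec <- suppressMessages(read_fossils(f))
  cleaned <- suppressMessages(clean_fossils(rec))
  rep <- cleaned$report
  expect_equal(unname(rep["n_input"]), 5)
  expect_equal(unname(rep["n_indeterminate"] + rep["n_duplicates"] +
                      rep["n_unassigned"] + rep["n_assigned"]),
               unname(rep["n_input"]))
})

test_that("cleaning output is stable under input row permutation", {
  rec <- toy_fossils()
  set.seed(82)
  perm <- rec[sample(nrow(rec)), ]
  a <- suppressMessages(clean_fossils(rec))$records
  b <- suppressMessages(clean_fossils(perm))$records
  key <- function(d) do.call(order, d[c("genus", "lon", "lat", "min_age")])
  a <- a[key(a), ]
  b <- b[key(b), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("interval series recovers planted regional faunas from fossils", {
  sc <- small_scenario(seed = 83)
  st <- simulate_regional_tree(sc)
  m <- simulate_ranges(sc, st$regions)
  lookup <- lattice_region_lookup(m)
  fos <- simulate_fossils(sc, st$regions, m, preservation = 1)
  cleaned <- suppressMessages(clean_fossils(fos))
  series <- suppressWarnings(
    interval_beta_series(cleaned$records, lookup, seed = 1))
  expect_equal(length(series), 5L)
  done <- !vapply(series, is.null, logical(1))
  expect_true(all(done))
  for (iv in names(series)) {
    expect_true(isSymmetric(series[[iv]]$beta))
    expect_s3_class(series[[iv]]$dendrogram, "hclust")
  }

  # identical faunas across regions give an all-zero matrix
  lookup_one <- make_region_lookup(data.frame(lon = 1, lat = 1), "only")
  rec_one <- data.frame(genus = c("g1", "g2"), lon = 1, lat = 1,
                        min_age = 40, max_age = 50)
  rec_one <- suppressMessages(assign_interval(rec_one))
  m_one <- region_genus_incidence(rec_one, lookup_one, "Eocene")
  expect_equal(unname(pairwise_beta_sim(m_one)), matrix(0, 1, 1))
})
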