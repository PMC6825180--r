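occ_df <- function(lon, lat, species = "myna",
                   date = "2017-06-01", source = "test") {
  data.frame(species = species, lon = lon, lat = lat, date = date,
             source = source, stringsAsFactors = FALSE)
}

test_that("deduplication collapses exact rows and keys on date", {
  a <- occ_df(34.8, 32.1)
  expect_equal(nrow(deduplicate(rbind(a, a))), 1)
  b <- rbind(occ_df(34.8, 32.1, date = "2017-06-01"),
             occ_df(34.8, 32.1, date = "2018-06-01"))
  expect_equal(nrow(deduplicate(b)), 2)
  # 10 rows with 3 duplicated pairs -> 7 distinct
  set.seed(1)
  base <- occ_df(runif(7, 34, 35), runif(7, 31, 32))
  ten <- rbind(base, base[c(2, 4, 6), ])
  expect_equal(nrow(deduplicate(ten)), 7)
  expect_equal(deduplicate(ten), base, ignore_attr = TRUE)
})

test_that("greedy thinning keeps the documented records", {
  # three collinear points at 0, 2, 4 km going north; 3-km filter keeps
  # the ends
  km_deg <- 1 / 110.574  # degrees latitude per km
  o <- occ_df(rep(34.5, 3), 32 + c(0, 2, 4) * km_deg)
  thinned <- thin_min_distance(o, 3)
  expect_equal(thinned$lat, o$lat[c(1, 3)])
  # single record untouched; zero radius untouched
  expect_equal(thin_min_distance(o[1, ], 3), o[1, ])
  expect_equal(thin_min_distance(o, 0), o)
})

test_that("thinning is idempotent and enforces the radius exhaustively", {
  set.seed(5)
  o <- occ_df(34.5 + rnorm(80, sd = 0.02), 32 + rnorm(80, sd = 0.02))
  for (r in c(0.5, 1.5, 3)) {
    t1 <- thin_min_distance(o, r)
    # exhaustive pairwise great-circle check
    for (i in seq_len(nrow(t1) - 1))
      for (j in (i + 1):nrow(t1))
        expect_gte(geosphere::distHaversine(
          c(t1$lon[i], t1$lat[i]), c(t1$lon[j], t1$lat[j])) / 1000, r)
    expect_equal(thin_min_distance(t1, r), t1)
  }
})

test_that("foraging-distance thinning saturates and looks up metadata", {
  set.seed(6)
  o <- occ_df(34.5 + rnorm(40, sd = 0.01), 32 + rnorm(40, sd = 0.01))
  # radius far beyond the extent diagonal -> one record survives
  expect_equal(nrow(thin_foraging_distance(o, 1000)), 1)
  # tiny radius -> all survive
  expect_equal(nrow(thin_foraging_distance(o, 1e-4)), nrow(o))
  meta <- data.frame(species = "sparrow", foraging_km = 2)
  expect_error(thin_foraging_distance(o, meta), "myna")
  expect_error(thin_foraging_distance(o, 0), "> 0")
})

test_that("home-range union answers membership queries correctly", {
  one <- occ_df(34.5, 32)
  r <- build_range(one, 3)
  km_deg <- 1 / 110.574
  expect_true(range_contains(r, 34.5, 32))              # the record itself
  expect_true(range_contains(r, 34.5, 32 + 2.9 * km_deg))
  expect_false(range_contains(r, 34.5, 32 + 3.1 * km_deg))
  # two records 10 km apart, 3-km buffers: the midpoint is outside
  two <- occ_df(rep(34.5, 2), 32 + c(0, 10 * km_deg))
  r2 <- build_range(two, 3)
  expect_false(range_contains(r2, 34.5, 32 + 5 * km_deg))
  expect_warning(r0 <- build_range(one[0, ], 3), "empty")
  expect_false(any(range_contains(r0, 34.5, 32)))
})

test_that("background sampling excludes the range and is seed-stable", {
  g <- predictor_grid(34, 31, 0.01, 20, 20,
                      layers = list(a = matrix(1, 20, 20)))
  focal <- occ_df(34.1, 31.1)
  r <- build_range(focal, 3)
  expect_equal(nrow(sample_background(g, r, 0)), 0)
  bg <- sample_background(g, r, 100, seed = 3)
  expect_equal(nrow(bg), 100)
  expect_equal(nrow(unique(bg)), 100)  # distinct cells
  # exhaustive membership oracle
  for (i in seq_len(nrow(bg)))
    expect_gt(geosphere::distHaversine(
      c(bg$lon[i], bg$lat[i]), c(34.1, 31.1)) / 1000, 3)
  expect_identical(bg, sample_background(g, r, 100, seed = 3))
  expect_error(sample_background(g, r, 10000),
               "only [0-9]+ valid cells")
})

test_that("interactor labelling matches per-site point-in-circle checks", {
  km_deg <- 1 / 110.574
  sites <- data.frame(lon = rep(34.5, 5),
                      lat = 32 + c(0, 1, 2, 5, 9) * km_deg)
  ra <- build_range(occ_df(34.5, 32), 2.5)
  rb <- build_range(occ_df(34.5, 32 + 9 * km_deg), 2.5)
  L <- label_interactors(sites, list(a = ra, b = rb))
  for (i in 1:5) {
    expect_equal(unname(L[i, "a"]),
                 as.integer(geosphere::distHaversine(
                   c(sites$lon[i], sites$lat[i]), c(34.5, 32)) / 1000
                   <= 2.5))
  }
  expect_equal(unname(L[, "b"]), c(0L, 0L, 0L, 0L, 1L))
  suppressWarnings(r_empty <- build_range(occ_df(34, 32)[0, ], 2))
  L2 <- label_interactors(sites, list(e = r_empty))
  expect_true(all(L2[, "e"] == 0))
})

test_that("design extraction standardizes, round-trips and drops masked", {
  g <- make_test_grid(seed = 2)
  cc <- grid_cell_centers(g)
  set.seed(9)
  sites <- cc[sample(nrow(cc), 60), c("lon", "lat")]
  des <- extract_design(g, sites, standardize = TRUE)
  expect_equal(unname(colMeans(des$X)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(des$X, 2, sd)), rep(1, 3), tolerance = 1e-12)
  raw <- extract_design(g, sites, standardize = FALSE)$X
  back <- sweep(sweep(des$X, 2, attr(des$X, "scale"), "*"), 2,
                attr(des$X, "center"), "+")
  expect_equal(as.numeric(back), as.numeric(raw), tolerance = 1e-12)

  # constant layer stays constant without standardization
  gc <- predictor_grid(0, 0, 1, 3, 3, layers = list(k = matrix(4, 3, 3)))
  Xc <- extract_design(gc, data.frame(lon = c(0.5, 1.5),
                                      lat = c(0.5, 1.5)),
                       standardize = FALSE)$X
  expect_true(all(Xc[, "k"] == 4))

  # masked cells are dropped with a message
  gm <- g; gm$mask[, ] <- TRUE; gm$mask[1:15, ] <- FALSE
  on_masked <- cc$row <= 15
  expect_message(
    desm <- extract_design(gm, cc[, c("lon", "lat")], standardize = FALSE),
    "dropped")
  expect_equal(nrow(desm$X), sum(!on_masked))
  gall <- g; gall$mask[, ] <- FALSE
  expect_error(extract_design(gall, sites), "masked")
})

test_that("date filtering matches brute-force comparison and warns on junk", {
  set.seed(4)
  dates <- sample(seq(as.Date("1997-01-01"), as.Date("2018-12-31"),
                      by = "day"), 200, replace = TRUE)
  o <- occ_df(runif(200, 34, 35), runif(200, 31, 33),
              date = as.character(dates))
  w <- filter_by_date(o, "2016-01-01", "2018-12-31")
  expect_equal(nrow(w), sum(dates >= as.Date("2016-01-01") &
                            dates <= as.Date("2018-12-31")))
  expect_equal(nrow(filter_by_date(o, "1900-01-01", "2100-01-01")), 200)
  expect_equal(nrow(filter_by_date(o, "1900-01-01", "1901-01-01")), 0)
  o$date[5] <- "not-a-date"
  expect_warning(f <- filter_by_date(o, "1900-01-01", "2100-01-01"),
                 "unparseable")
  expect_equal(nrow(f), 199)
  expect_error(filter_by_date(o, "2018-01-01", "2016-01-01"), "start")
})

test_that("site-table assembly sets the focal column by role", {
  g <- make_test_grid(seed = 41)
  tr <- make_test_truth(J = 3)
  st <- simulate_community(g, tr, 600, seed = 1)
  occ <- sample_presence_only(st, tr, seed = 2)
  focal <- thin_min_distance(deduplicate(occ$sp1), 0.3)
  fr <- build_range(focal, tr$home_range_km[1])
  ir <- list(sp2 = build_range(occ$sp2, 0.8),
             sp3 = build_range(occ$sp3, 0.8))
  tab <- build_site_table(g, focal, fr, ir, n_background = 150, seed = 3)
  expect_s3_class(tab, "site_table")
  expect_equal(unname(tab$Y[, "focal"]),
               as.integer(tab$sites$role == "focal-presence"))
  expect_equal(colnames(tab$Y), c("focal", "sp2", "sp3"))
  expect_false(anyNA(tab$X))
  counts <- attr(tab, "counts")
  expect_equal(unname(counts["background"]), 150)
})
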