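fixture_path <- function(name) system.file("extdata", name, package = "podomap")

test_that("regional survey fixture reproduces the published totals exactly", {
  t1 <- read_region_survey_csv(fixture_path("cameroon_region_surveys.csv"))
  tot <- survey_totals(t1)
  expect_identical(tot$total_screened, 214729L)
  expect_identical(tot$total_cases, 882L)
  expect_equal(tot$prevalence_pct, 0.41)
  expect_equal(tot$wald_ci_pct, c(0.38, 0.44))
  expect_equal(tot$clopper_pearson_ci_pct, c(0.38, 0.44))
  expect_equal(sum(t1$clusters), 748)
})

test_that("community summary counts zero-case communities", {
  s <- data.frame(community_id = as.character(1:8), x_km = 0, y_km = 0,
                  n_screened = c(120, 80, 100, 300, 50, 200, 150, 90),
                  n_cases = c(0, 2, 0, 5, 0, 1, 0, 0))
  summ <- survey_summary(s)
  expect_equal(summ$zero_case_communities, 5)
  expect_equal(summ$zero_case_share_pct, 62.5)
  expect_equal(summ$share_ge100_pct, 62.5)
  bad <- s; bad$n_cases[1] <- 999
  expect_error(survey_summary(bad), "exceeds")
})

test_that("adult population scaling validates and multiplies", {
  pop <- flat_grid(4, 4, 1000)
  expect_equal(adult_population(pop, 1)$values, pop$values)
  expect_equal(adult_population(pop, 0)$values, matrix(0, 4, 4))
  expect_equal(adult_population(pop, 0.55)$values, matrix(550, 4, 4))
  expect_error(adult_population(pop, 1.2), "outside")
})

test_that("case surfaces are exact cell-wise products and refuse misalignment", {
  set.seed(20)
  nr <- 6; nc <- 7
  mk <- function() raster_grid(matrix(runif(nr * nc, 0, 0.05), nr, nc),
                               xmin = 0, ymax = nr, cellsize = 1)
  prev <- list(mean = mk(), ci_low = mk(), ci_high = mk())
  adults <- raster_grid(matrix(runif(nr * nc, 0, 2000), nr, nc),
                        xmin = 0, ymax = nr, cellsize = 1)
  cs <- cases_surface(prev, adults)
  expect_equal(cs$mean$values, prev$mean$values * adults$values, tolerance = 1e-12)
  expect_equal(cs$low$values, prev$ci_low$values * adults$values, tolerance = 1e-12)

  shifted <- raster_grid(adults$values, xmin = 1, ymax = nr, cellsize = 1)
  expect_error(cases_surface(prev, shifted), "misaligned")
})

test_that("zonal aggregation conserves totals and reports unassigned cells", {
  set.seed(21)
  nr <- 10; nc <- 10
  prev <- list(mean = raster_grid(matrix(runif(100, 0, 0.02), nr, nc),
                                  xmin = 0, ymax = nr, cellsize = 1))
  prev$ci_low <- prev$mean; prev$ci_high <- prev$mean
  adults <- raster_grid(matrix(runif(100, 100, 500), nr, nc),
                        xmin = 0, ymax = nr, cellsize = 1)
  cs <- cases_surface(prev, adults)
  rect <- function(x1, x2, y1, y2) {
    list(cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1)))
  }
  whole <- admin_polygons(list(all = rect(0, 10, 0, 10)))
  tab <- aggregate_burden(cs, adults, whole)
  expect_equal(sum(tab$cases_mean), sum(cs$mean$values), tolerance = 1e-9)
  expect_equal(tab$cases_mean[tab$name == "unassigned"], 0)

  halves <- admin_polygons(list(west = rect(0, 5, 0, 10),
                                east = rect(5, 10, 0, 10)))
  tab2 <- aggregate_burden(cs, adults, halves)
  expect_equal(sum(tab2$cases_mean), sum(cs$mean$values), tolerance = 1e-9)
  expect_equal(sum(tab2$population_at_risk), sum(adults$values), tolerance = 1e-9)

  partial <- admin_polygons(list(corner = rect(0, 3, 7, 10)))
  tab3 <- aggregate_burden(cs, adults, partial)
  expect_equal(tab3$cases_mean[tab3$name == "unassigned"],
               sum(cs$mean$values) - tab3$cases_mean[1], tolerance = 1e-9)

  overlap <- admin_polygons(list(a = rect(0, 6, 0, 10), b = rect(4, 10, 0, 10)))
  expect_error(aggregate_burden(cs, adults, overlap), "overlap")

  # scale equivariance: doubling the population doubles every column
  adults2 <- adults; adults2$values <- adults$values * 2
  cs2 <- cases_surface(prev, adults2)
  tab4 <- aggregate_burden(cs2, adults2, halves)
  expect_equal(tab4$cases_mean, tab2$cases_mean * 2, tolerance = 1e-12)
  expect_equal(tab4$population_at_risk, tab2$population_at_risk * 2,
               tolerance = 1e-12)
})

test_that("conservation holds across random rectangle partitions", {
  set.seed(22)
  prev <- list(mean = raster_grid(matrix(runif(144, 0, 0.05), 12, 12),
                                  xmin = 0, ymax = 12, cellsize = 1))
  prev$ci_low <- prev$mean; prev$ci_high <- prev$mean
  adults <- raster_grid(matrix(runif(144, 10, 100), 12, 12),
                        xmin = 0, ymax = 12, cellsize = 1)
  cs <- cases_surface(prev, adults)
  rect <- function(x1, x2, y1, y2) {
    list(cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1)))
  }
  for (k in 1:5) {
    sx <- sort(c(0, runif(2, 1, 11), 12))
    units <- lapply(seq_len(3), function(i) rect(sx[i], sx[i + 1], 0, 12))
    names(units) <- paste0("strip", 1:3)
    tab <- aggregate_burden(cs, adults, admin_polygons(units))
    expect_equal(sum(tab$cases_mean), sum(cs$mean$values), tolerance = 1e-6)
  }
})

test_that("regional burden fixture reproduces the published shares", {
  t2 <- read_burden_csv(fixture_path("cameroon_region_burden.csv"))
  expect_equal(burden_share(t2, c("Central", "Littoral", "North", "North West")),
               61.2)
  expect_equal(burden_share(t2, "Central"), 17.6)
  expect_equal(burden_share(t2, "North West", column = "population_at_risk"),
               32.2)
  summ <- summarize_endemicity(t2)
  expect_equal(summ$shares$cases_share_pct[summ$shares$name == "Central"], 17.6)
  expect_equal(summ$shares$par_share_pct[summ$shares$name == "North West"], 32.2)
  expect_equal(summ$counts$n_units[summ$counts$threshold == 500], 10)
  expect_equal(summ$largest_unit, "Central")
  empty <- summarize_endemicity(t2[0, ])
  expect_equal(empty$counts$n_units, c(0L, 0L))
})

test_that("GeoJSON polygons round-trip through aggregation", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(name = "west"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(0, 0), list(5, 0), list(5, 10), list(0, 10), list(0, 0))))),
    list(type = "Feature", properties = list(name = "east"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(5, 0), list(10, 0), list(10, 10), list(5, 10), list(5, 0)))))))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  admin <- read_geojson_polygons(path)
  expect_equal(vapply(admin, `[[`, "", "name"), c("west", "east"))
  prev <- list(mean = flat_grid(10, 10, 0.01))
  prev$ci_low <- prev$mean; prev$ci_high <- prev$mean
  adults <- flat_grid(10, 10, 100)
  tab <- aggregate_burden(cases_surface(prev, adults), adults, admin)
  expect_equal(tab$cases_mean[1:2], c(50, 50))
})
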