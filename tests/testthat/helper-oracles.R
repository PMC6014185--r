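# Independent brute-force oracles used to pin down the optimized
# implementations. These deliberately use the slowest, most literal form of
# each definition.

# AUC as the all-pairs concordance count (ties get half credit)
oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# Gaussian-sum KDE over cell centres (kernels sit at the centres of the
# cells containing the occurrences, matching count-then-smooth)
oracle_kde <- function(occurrences, grid, bandwidth) {
  loc <- locate_cells(grid, occurrences$x, occurrences$y)
  cc <- cell_centres(grid)
  out <- matrix(0, nrow(grid$values), ncol(grid$values))
  for (k in which(loc$inside)) {
    px <- grid$xmin + (loc$col[k] - 0.5) * grid$cellsize
    py <- grid$ymax - (loc$row[k] - 0.5) * grid$cellsize
    d2 <- (cc$x - px)^2 + (cc$y - py)^2
    out[cbind(cc$row, cc$col)] <- out[cbind(cc$row, cc$col)] +
      exp(-d2 / (2 * bandwidth^2))
  }
  out[is.na(grid$values)] <- NA_real_
  out / sum(out, na.rm = TRUE)
}

# per-cell minimum distance by explicit double loop
oracle_distance <- function(features, grid) {
  cc <- cell_centres(grid)
  out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  for (i in seq_len(nrow(cc))) {
    dmin <- Inf
    for (k in seq_len(nrow(features))) {
      dmin <- min(dmin, sqrt((cc$x[i] - features$x[k])^2 +
                               (cc$y[i] - features$y[k])^2))
    }
    out[cc$row[i], cc$col[i]] <- dmin
  }
  loc <- locate_cells(grid, features$x, features$y)
  ok <- loc$inside
  out[cbind(loc$row[ok], loc$col[ok])] <- 0
  out
}

# nearest source centre by exhaustive search per target cell
oracle_resample <- function(src, target) {
  scc <- cell_centres(src)
  tcc <- cell_centres(target)
  out <- matrix(NA_real_, nrow(target$values), ncol(target$values))
  for (i in seq_len(nrow(tcc))) {
    d2 <- (scc$x - tcc$x[i])^2 + (scc$y - tcc$y[i])^2
    j <- which.min(d2)
    out[tcc$row[i], tcc$col[i]] <- src$values[scc$row[j], scc$col[j]]
  }
  out
}

# Horn 3x3 kernel, written independently as an explicit per-cell loop with
# index clamping at the borders
oracle_horn_slope <- function(elev, z_scale = 1) {
  z <- elev$values * z_scale
  nr <- nrow(z); nc <- ncol(z); cs <- elev$cellsize
  cl <- function(i, n) min(max(i, 1), n)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    zz <- function(dr, dc) z[cl(r + dr, nr), cl(c + dc, nc)]
    gx <- ((zz(-1, 1) + 2 * zz(0, 1) + zz(1, 1)) -
             (zz(-1, -1) + 2 * zz(0, -1) + zz(1, -1))) / (8 * cs)
    gy <- ((zz(1, -1) + 2 * zz(1, 0) + zz(1, 1)) -
             (zz(-1, -1) + 2 * zz(-1, 0) + zz(-1, 1))) / (8 * cs)
    out[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  out
}

# partial dependence straight from its definition
oracle_partial_dependence <- function(learner, data, covariate, values) {
  sapply(values, function(v) {
    df <- as.data.frame(data)[, learner$covariates, drop = FALSE]
    df[[covariate]] <- v
    mean(predict(learner, df))
  })
}

# small helper worlds shared across tests
tiny_world <- function(seed = 5, grid = c(30, 30), n_comm = 120) {
  cfg <- synth_config(grid_shape = grid, n_covariates = 2, covariate_ranges = 10,
                      beta = c(logit(0.01), 1, -1), sigma2 = 0.5, phi = 8,
                      tau2 = 0.1, n_communities = n_comm,
                      n_per_community_range = c(100, 300),
                      oversample_fraction = 0.6,
                      oversample_region = list(row = c(1, grid[1] %/% 2),
                                               col = c(1, grid[2] %/% 2)),
                      seed = seed)
  simulate_world(cfg)
}

flat_grid <- function(nr = 10, nc = 10, value = 0, cellsize = 1) {
  raster_grid(matrix(value, nr, nc), xmin = 0, ymax = nr * cellsize,
              cellsize = cellsize)
}
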