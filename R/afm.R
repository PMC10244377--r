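## AFM force-curve analysis: conical (Sneddon) Hertz model, contact-point
## estimation, per-pixel modulus fitting, modulus maps, colony-center
## extraction, MAD outlier normalization, group comparison.

#' Conical-indenter Hertz force
#'
#' Closed form for a rigid cone indenting an elastic half-space
#' (Sneddon): F = (2/pi) * tan(theta) * E / (1 - nu^2) * delta^2.
#'
#' @param E Young's modulus, Pa.
#' @param delta Indentation depth(s), m (must be >= 0).
#' @param nu Poisson's ratio (default 0.5, incompressible).
#' @param theta Half-cone angle in degrees (default 22).
#' @return Force in N, same length as `delta`.
#' @examples
#' hertz_cone_force(1000, 3e-7)  # ~3.1e-11 N
#' @export
hertz_cone_force <- function(E, delta, nu = 0.5, theta = 22) {
  stopifnot(E > 0, nu >= 0, nu <= 0.5, theta > 0, theta < 90)
  if (any(delta < 0)) stop("indentation must be non-negative")
  (2 / pi) * tan(theta * pi / 180) * E / (1 - nu^2) * delta^2
}

#' Estimate the contact point of a force curve
#'
#' Two stages: (1) a baseline (mean and noise SD of the first
#' `baseline_frac` of the approach curve) gives a coarse contact index as
#' the first position where force exceeds baseline + `threshold` * SD for
#' `persist` consecutive samples; (2) the contact position is refined by
#' minimizing the residual sum of squares of the piecewise model
#' F(z) = a * max(z - z0, 0)^2 + c over z0 (a, c profiled out by linear
#' least squares).
#'
#' @param z Piezo position, m (increasing; approach segment).
#' @param force Measured force, N (same length).
#' @param baseline_frac Fraction of the curve treated as pre-contact
#'   baseline (default 0.3).
#' @param threshold Detection threshold in baseline noise SDs (default 3).
#' @param persist Consecutive samples required above threshold (default 5).
#' @param refine Run the RSS refinement stage (default `TRUE`).
#' @return List with `index` (coarse contact index), `z0` (refined contact
#'   position, m), `offset` (baseline force, N), `noise_sd` (N).
#' @export
estimate_contact_point <- function(z, force, baseline_frac = 0.3,
                                   threshold = 3, persist = 5,
                                   refine = TRUE) {
  n <- length(z)
  stopifnot(n == length(force), n >= 20)
  nb <- max(5L, floor(baseline_frac * n))
  b0 <- mean(force[seq_len(nb)])
  sig <- sd(force[seq_len(nb)])
  eps <- max(sig, 1e-15)
  above <- force > b0 + threshold * eps
  ## first run of `persist` consecutive TRUEs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persist)
  if (!length(hit)) {
    stop("no post-contact data: force never exceeds baseline + ",
         threshold, " SD for ", persist, " consecutive samples")
  }
  idx <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  z0 <- z[idx]
  if (refine) {
    rss <- function(z0c) {
      d <- pmax(z - z0c, 0)
      X <- cbind(1, d^2)
      fit <- stats::lm.fit(X, force)
      sum(fit$residuals^2)
    }
    ## threshold detection lags true contact for soft samples (the force
    ## rises slowly through the noise floor), so search a wide window:
    ## coarse grid first, then local optimization around the best point
    lo <- max(z[1], z0 - 6e-7)
    hi <- min(z[n - 10L], z0 + 1e-7)
    if (hi > lo) {
      grid <- seq(lo, hi, length.out = 41)
      vals <- vapply(grid, rss, numeric(1))
      b <- which.min(vals)
      blo <- grid[max(1, b - 1)]; bhi <- grid[min(length(grid), b + 1)]
      opt <- optimize(rss, c(blo, bhi), tol = 1e-13)
      z0 <- opt$minimum
    }
  }
  list(index = idx, z0 = z0, offset = b0, noise_sd = sig)
}

#' Fit Young's modulus to a force curve (conical Hertz model)
#'
#' With the contact point fixed, the model F = a * delta^2 + c is linear
#' in (a, c); the fit is ordinary least squares over points with
#' indentation inside `delta_range` (default 150-500 nm), and
#' E = a * pi * (1 - nu^2) / (2 tan theta). The force offset c is free, so
#' the estimate is invariant to a constant force shift.
#'
#' @param z,force Approach curve (m, N).
#' @param contact Output of [estimate_contact_point()]; estimated when
#'   `NULL`.
#' @param nu,theta Fixed Poisson ratio and half-cone angle (degrees).
#' @param delta_range Indentation window used for fitting, m (default
#'   `c(150e-9, 500e-9)`).
#' @param min_points Below this many in-range points the pixel is flagged
#'   unfit (`E = NA`), not an error. Default 10.
#' @return List with `E_Pa`, `E_kPa`, `r_squared`, `n_points`, `offset`,
#'   `z0`, `ok`.
#' @export
fit_modulus <- function(z, force, contact = NULL, nu = 0.5, theta = 22,
                        delta_range = c(150e-9, 500e-9), min_points = 10) {
  if (is.null(contact)) contact <- estimate_contact_point(z, force)
  delta <- z - contact$z0
  in_rng <- delta >= delta_range[1] & delta <= delta_range[2]
  if (sum(in_rng) < min_points) {
    return(list(E_Pa = NA_real_, E_kPa = NA_real_, r_squared = NA_real_,
                n_points = sum(in_rng), offset = NA_real_,
                z0 = contact$z0, ok = FALSE))
  }
  d2 <- delta[in_rng]^2
  f <- force[in_rng]
  fit <- lm(f ~ d2)
  a <- unname(coef(fit)[2])
  E <- a * pi * (1 - nu^2) / (2 * tan(theta * pi / 180))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(E_Pa = E, E_kPa = E / 1000, r_squared = r2,
       n_points = sum(in_rng), offset = unname(coef(fit)[1]),
       z0 = contact$z0, ok = is.finite(E) && E > 0)
}

#' Fit a grid of force curves into a modulus map
#'
#' Per-pixel Hertz fits assembled on the acquisition grid, plus a relative
#' height image derived from the piezo position at maximum force (higher
#' surface contacts earlier, so height = -z(at max force), shifted so the
#' minimum is zero).
#'
#' @param curve_set A `force_curve_set`: list with `curves` (list of
#'   lists with `z`, `force`, `row`, `col`) and `dims` `c(nrow, ncol)`.
#' @param nu,theta,delta_range Passed to [fit_modulus()].
#' @return List with `modulus` (kPa matrix), `r_squared` (matrix),
#'   `height` (m, matrix, relative) and `n_failed`.
#' @export
build_modulus_map <- function(curve_set, nu = 0.5, theta = 22,
                              delta_range = c(150e-9, 500e-9)) {
  dims <- curve_set$dims
  modulus <- r2 <- height <- matrix(NA_real_, dims[1], dims[2])
  n_failed <- 0L
  for (cv in curve_set$curves) {
    fit <- tryCatch(
      fit_modulus(cv$z, cv$force, nu = nu, theta = theta,
                  delta_range = delta_range),
      error = function(e) NULL
    )
    if (is.null(fit) || !isTRUE(fit$ok)) {
      n_failed <- n_failed + 1L
      next
    }
    modulus[cv$row, cv$col] <- fit$E_kPa
    r2[cv$row, cv$col] <- fit$r_squared
    height[cv$row, cv$col] <- -cv$z[which.max(cv$force)]
  }
  if (any(is.finite(height))) {
    height <- height - min(height, na.rm = TRUE)
  }
  list(modulus = modulus, r_squared = r2, height = height,
       n_failed = n_failed)
}

#' Extract modulus values from colony centers
#'
#' The colony mask is the set of pixels whose height exceeds a relative
#' threshold between the image minimum and maximum; the center region is
#' that mask eroded by `erode_margin` pixels (8-neighborhood). Modulus
#' values inside the center region are returned.
#'
#' @param modulus kPa matrix (from [build_modulus_map()]).
#' @param height Height matrix, same shape.
#' @param rel_threshold Relative height threshold in (0, 1); default 0.5.
#' @param erode_margin Erosion margin in pixels (default 1); 0 means the
#'   full mask.
#' @return Numeric vector of modulus values (kPa); the center mask is
#'   attached as attribute `"mask"`. Empty with a warning when no colony
#'   is found.
#' @export
colony_center_values <- function(modulus, height, rel_threshold = 0.5,
                                 erode_margin = 1) {
  stopifnot(all(dim(modulus) == dim(height)))
  rng <- range(height, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps * 10) {
    warning("flat height image: no colony detected")
    out <- numeric(0)
    attr(out, "mask") <- matrix(FALSE, nrow(height), ncol(height))
    return(out)
  }
  mask <- !is.na(height) & height >= rng[1] + rel_threshold * diff(rng)
  ## erode toward the colony center, but never to emptiness: on small
  ## grids the full margin can swallow the mask, so back off
  for (k in seq_len(erode_margin)) {
    eroded <- erode_mask(mask)
    if (!any(eroded)) {
      warning("erosion margin ", erode_margin, " would empty the colony ",
              "mask; stopped at margin ", k - 1L)
      break
    }
    mask <- eroded
  }
  vals <- modulus[mask & is.finite(modulus)]
  if (!length(vals)) warning("colony center region is empty")
  attr(vals, "mask") <- mask
  vals
}

## one-step binary erosion, 8-neighborhood; outside the grid counts as
## background so image borders erode
erode_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  out <- mask
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- all(padded[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

#' MAD normalization with outlier flagging
#'
#' v' = (v - median(v)) / MAD(v), with the MAD scaled by 1.4826 for
#' normal consistency; values with |v'| > `cutoff` are flagged outliers.
#'
#' @param values Numeric vector (kPa).
#' @param cutoff Outlier cutoff on the normalized scale (default 3.5).
#' @return List with `raw`, `normalized`, `outlier` (logical), `median`,
#'   `mad`.
#' @export
mad_normalize <- function(values, cutoff = 3.5) {
  values <- values[is.finite(values)]
  m <- median(values)
  s <- mad(values)  # 1.4826 * median(|v - median|)
  if (s == 0) stop("MAD is zero: input has no variation")
  normalized <- (values - m) / s
  list(raw = values, normalized = normalized,
       outlier = abs(normalized) > cutoff, median = m, mad = s)
}

#' Compare stiffness between groups
#'
#' Kruskal-Wallis omnibus test plus Games-Howell pairwise comparisons
#' (Welch-type, studentized-range reference), with per-group medians and
#' quartiles. Optionally drops MAD-flagged outliers first.
#'
#' @param groups Named list of modulus vectors (kPa).
#' @param drop_outliers Remove values flagged by [mad_normalize()] within
#'   each group before testing (default `FALSE`).
#' @param mad_cutoff Cutoff passed to [mad_normalize()].
#' @return List with `kruskal`, `games_howell`, `summary`.
#' @export
compare_stiffness <- function(groups, drop_outliers = FALSE,
                              mad_cutoff = 3.5) {
  groups <- lapply(groups, function(v) v[is.finite(v)])
  if (drop_outliers) {
    groups <- lapply(groups, function(v) {
      mn <- mad_normalize(v, cutoff = mad_cutoff)
      mn$raw[!mn$outlier]
    })
  }
  summ <- do.call(rbind, lapply(names(groups), function(gname) {
    v <- groups[[gname]]
    data.frame(group = gname, n = length(v), median = median(v),
               q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  list(
    kruskal = kruskal_wallis(groups),
    games_howell = games_howell(groups),
    summary = summ
  )
}

#' Write force curves as a single grid TSV
#'
#' Long format with columns `pixel_row`, `pixel_col`, `z_m`, `force_n`.
#'
#' @param curve_set `force_curve_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_force_curves <- function(curve_set, path) {
  tab <- do.call(rbind, lapply(curve_set$curves, function(cv) {
    data.frame(pixel_row = cv$row, pixel_col = cv$col,
               z_m = cv$z, force_n = cv$force)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read force curves from a grid TSV
#'
#' @param path TSV from [write_force_curves()].
#' @return `force_curve_set` (list with `curves`, `dims`).
#' @export
read_force_curves <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pixel_row", "pixel_col", "z_m", "force_n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("force-curve table missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(tab$pixel_row, tab$pixel_col)
  curves <- lapply(split(tab, key), function(d) {
    list(z = d$z_m, force = d$force_n,
         row = d$pixel_row[1], col = d$pixel_col[1])
  })
  list(curves = unname(curves),
       dims = c(max(tab$pixel_row), max(tab$pixel_col)))
}
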