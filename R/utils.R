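# Internal numeric helpers: Gaussian / LoG filtering, Otsu, greedy point
# matching. Volumes are (nz, ny, nx) arrays, z fastest.

gaussian_kernel1d <- function(sigma_vox, truncate = 3) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' @noRd
smooth_gaussian3d <- function(vol, sigma_vox) {
  # separable Gaussian; sigma_vox length 3 (z, y, x) in voxel units
  d <- dim(vol)
  out <- as.numeric(vol)
  for (ax in 0:2) {
    s <- sigma_vox[ax + 1]
    if (s > 0 && d[ax + 1] > 1) {
      out <- conv_axis_cpp(out, as.integer(d), ax, gaussian_kernel1d(s))
    }
  }
  array(out, d)
}

#' @noRd
log_response3d <- function(vol, sigma_vox) {
  # scale-normalised Laplacian of Gaussian, sign-flipped so bright blobs give
  # positive responses: -sum_i sigma_i^2 d2/dx_i^2 (G * f), in voxel units
  d <- dim(vol)
  sm <- smooth_gaussian3d(vol, sigma_vox)
  resp <- array(0, d)
  lap <- c(1, -2, 1)
  for (ax in 0:2) {
    if (d[ax + 1] > 1 && sigma_vox[ax + 1] > 0) {
      resp <- resp + sigma_vox[ax + 1]^2 *
        array(conv_axis_cpp(as.numeric(sm), as.integer(d), ax, lap), d)
    }
  }
  list(response = -resp, smoothed = sm)
}

#' Otsu threshold of a numeric sample
#'
#' Histogram-based threshold maximising between-class variance, computed on
#' 256 bins via [EBImage::otsu()] after rescaling to the unit interval.
#'
#' @param values numeric vector (finite).
#' @param levels number of histogram bins.
#' @return threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, levels = 256) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || diff(range(values)) == 0) {
    stop("otsu_threshold: values are constant; supply a manual threshold")
  }
  lo <- min(values); hi <- max(values)
  v01 <- (values - lo) / (hi - lo)
  t01 <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1)),
                       range = c(0, 1), levels = levels)
  lo + as.numeric(t01) * (hi - lo)
}

#' @noRd
greedy_match_points <- function(a, b, radius) {
  # greedy nearest matching between point sets (rows), distance <= radius;
  # returns two index vectors. Used for spot scoring.
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(a = integer(0), b = integer(0)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  ord <- order(d2)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  ia <- integer(0); ib <- integer(0)
  r2 <- radius^2
  for (k in ord) {
    if (d2[k] > r2) break
    i <- (k - 1) %% nrow(a) + 1
    j <- (k - 1) %/% nrow(a) + 1
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  list(a = ia, b = ib)
}

# deterministic number formatting for CSV output (6 significant digits)
fmt_num <- function(x) {
  out <- character(length(x))
  na <- is.na(x)
  out[na] <- ""
  v <- x[!na]
  int <- v == round(v) & abs(v) < 1e15
  s <- character(length(v))
  s[int] <- format(v[int], scientific = FALSE, trim = TRUE)
  s[!int] <- formatC(signif(v[!int], 6), format = "g", digits = 6)
  out[!na] <- s
  out
}

# write a data.frame as deterministic CSV (numbers at 6 significant digits,
# missing values as empty fields)
write_csv_stable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    } else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con, sep = "\n")
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
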