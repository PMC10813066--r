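#' Drop categorical variables with too little variability
#'
#' Removes categorical columns that cannot support a factorial analysis:
#' fewer than two observed levels (always absent or always present), or
#' any observed level carried by exactly one record (a single presence or
#' a single absence), which would dominate an axis on its own.
#' Continuous columns are kept as-is.
#'
#' @param table Data frame mixing numeric and factor/character columns.
#' @return The filtered data frame.
#' @export
filter_variables <- function(table) {
  stopifnot(is.data.frame(table))
  keep <- vapply(names(table), function(nm) {
    x <- table[[nm]]
    if (is.numeric(x)) return(TRUE)
    tab <- table(x[!is.na(x)])
    tab <- tab[tab > 0]
    length(tab) >= 2 && min(tab) > 1
  }, TRUE)
  out <- table[, keep, drop = FALSE]
  if (ncol(out) == 0) stop("no variables left after the variability filter")
  out
}

famd_encode <- function(table) {
  is_num <- vapply(table, is.numeric, TRUE)
  Xc <- NULL; cont_names <- character()
  if (any(is_num)) {
    Xc <- as.matrix(table[, is_num, drop = FALSE])
    cont_names <- names(table)[is_num]
    mu <- colMeans(Xc)
    sig <- sqrt(colMeans(sweep(Xc, 2, mu)^2))   # population sd
    if (any(sig < 1e-12))
      stop("zero-variance continuous column: ",
           cont_names[which(sig < 1e-12)[1]])
    Xc <- sweep(sweep(Xc, 2, mu), 2, sig, "/")
  }
  Zs <- NULL; level_names <- character(); level_var <- character()
  level_p <- numeric()
  cat_names <- names(table)[!is_num]
  for (nm in cat_names) {
    f <- droplevels(as.factor(table[[nm]]))
    if (nlevels(f) < 2)
      stop("categorical column with a single level: ", nm)
    Z <- stats::model.matrix(~ f - 1)
    p <- colMeans(Z)
    M <- sweep(sweep(Z, 2, p), 2, sqrt(p), "/")
    Zs <- cbind(Zs, M)
    level_names <- c(level_names, paste(nm, levels(f), sep = "="))
    level_var <- c(level_var, rep(nm, nlevels(f)))
    level_p <- c(level_p, p)
  }
  list(M = cbind(Xc, Zs), n_cont = length(cont_names),
       cont_names = cont_names, cat_names = cat_names,
       level_names = level_names, level_var = level_var, level_p = level_p)
}

#' Factor Analysis of Mixed Data
#'
#' A from-scratch FAMD: continuous columns are standardized to unit
#' (population) variance, each categorical level indicator is divided by
#' the square root of its proportion and centred, and the combined matrix
#' (weighted by \eqn{1/\sqrt{n}}) is decomposed by SVD. With only
#' continuous columns this reduces exactly to a standardized principal
#' component analysis; with only categorical columns the eigenvalues are
#' those of multiple correspondence analysis scaled by the number of
#' variables. The total inertia equals the number of continuous columns
#' plus the sum over categorical columns of (levels - 1).
#'
#' @param table Complete data frame (no missing cells; see
#'   [impute_missing()]), at least 3 rows.
#' @param n_axes Number of principal axes to retain (default 5, capped at
#'   the rank).
#' @return A `famd` object: `eigenvalues`, `pct_variance`, `row_coords`,
#'   `cont_coords` (correlations of continuous variables with the axes),
#'   `level_coords` (category barycentres), `cos2_rows`, `cos2_levels`,
#'   `inertia_total`.
#' @examples
#' d <- data.frame(a = rnorm(10), b = rnorm(10),
#'                 g = rep(c("x", "y"), 5))
#' fit_famd(d, n_axes = 2)
#' @export
fit_famd <- function(table, n_axes = 5) {
  stopifnot(is.data.frame(table), nrow(table) >= 3)
  if (anyNA(table)) stop("table has missing cells; impute first")
  enc <- famd_encode(table)
  n <- nrow(table)
  M <- enc$M / sqrt(n)
  sv <- svd(M)
  pos <- sv$d > 1e-10
  eig <- sv$d[pos]^2
  total <- enc$n_cont +
    sum(tapply(enc$level_p, enc$level_var, length) - 1)
  k <- min(n_axes, sum(pos))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  row_coords <- sqrt(n) * U %*% diag(d, k)
  rownames(row_coords) <- rownames(table)
  colnames(row_coords) <- paste0("Axis", seq_len(k))
  row_full <- n * rowSums(M^2)
  cos2_rows <- row_coords^2 / row_full

  cont_coords <- level_coords <- cos2_levels <- NULL
  if (enc$n_cont > 0) {
    cont_coords <- V[seq_len(enc$n_cont), , drop = FALSE] %*% diag(d, k)
    dimnames(cont_coords) <- list(enc$cont_names, colnames(row_coords))
  }
  if (length(enc$level_names)) {
    iv <- enc$n_cont + seq_along(enc$level_names)
    Vq <- V[iv, , drop = FALSE]
    level_coords <- sweep(Vq %*% diag(d^2, k), 1,
                          sqrt(enc$level_p), "/")
    # squared distance of a category barycentre to the origin over the
    # full space: sum over all axes
    Vfull <- sv$v[iv, pos, drop = FALSE]
    full <- rowSums(sweep(Vfull %*% diag(sv$d[pos]^2, sum(pos)), 1,
                          sqrt(enc$level_p), "/")^2)
    cos2_levels <- level_coords^2 / full
    dimnames(level_coords) <- list(enc$level_names, colnames(row_coords))
    dimnames(cos2_levels) <- dimnames(level_coords)
  }
  structure(list(eigenvalues = eig,
                 pct_variance = 100 * eig / total,
                 inertia_total = total,
                 row_coords = row_coords,
                 cont_coords = cont_coords,
                 level_coords = level_coords,
                 cos2_rows = cos2_rows,
                 cos2_levels = cos2_levels,
                 n_cont = enc$n_cont, cat_names = enc$cat_names,
                 n = n, call = match.call()),
            class = "famd")
}

#' @export
print.famd <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat(sprintf(
    "FAMD of %d rows (%d continuous, %d categorical variables); total inertia %.2f\n",
    x$n, x$n_cont, length(x$cat_names), x$inertia_total))
  tab <- rbind(eigenvalue = x$eigenvalues[seq_len(k)],
               `% variance` = x$pct_variance[seq_len(k)])
  colnames(tab) <- paste0("Axis", seq_len(k))
  print(round(tab, 3))
  invisible(x)
}

#' @export
summary.famd <- function(object, ...) {
  print(object)
  cat("\ncumulative % variance:\n")
  print(round(cumsum(object$pct_variance), 1))
  invisible(object)
}

#' Factorial map with per-group convex hulls
#'
#' Plots row coordinates on a pair of principal axes and overlays the
#' convex hull of each group, the standard display for inspecting how
#' etiology groups separate in the mixed-data factorial space.
#'
#' @param x A `famd` object.
#' @param axes Length-2 integer vector of axes to display.
#' @param groups Optional factor of row groups (hulls drawn per level).
#' @param level_cos2 Optional cut-off: categorical levels whose quality
#'   of representation (cos2) on the displayed axes reaches this value
#'   are labelled on the map (display only).
#' @param ... Passed to `plot()`.
#' @export
plot.famd <- function(x, axes = c(1, 2), groups = NULL,
                      level_cos2 = NULL, ...) {
  xy <- x$row_coords[, axes, drop = FALSE]
  labs <- sprintf("Axis %d (%.1f%%)", axes, x$pct_variance[axes])
  graphics::plot(xy, xlab = labs[1], ylab = labs[2], pch = 19,
                 col = if (is.null(groups)) 1 else as.integer(as.factor(groups)),
                 ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  if (!is.null(groups)) {
    g <- as.factor(groups)
    for (lev in levels(g)) {
      pts <- xy[g == lev, , drop = FALSE]
      if (nrow(pts) >= 3) {
        h <- grDevices::chull(pts)
        graphics::polygon(pts[h, ], border = as.integer(factor(lev, levels(g))),
                          lty = 2)
      }
    }
    graphics::legend("topright", legend = levels(g), col = seq_len(nlevels(g)),
                     pch = 19, bty = "n")
  }
  if (!is.null(level_cos2) && !is.null(x$level_coords)) {
    q <- rowSums(x$cos2_levels[, axes, drop = FALSE])
    show <- q >= level_cos2
    if (any(show))
      graphics::text(x$level_coords[show, axes, drop = FALSE],
                     labels = rownames(x$level_coords)[show],
                     col = "grey30", cex = 0.8, font = 3)
  }
  invisible(x)
}

#' Iterative imputation of missing values in mixed data
#'
#' Fills missing cells by iterating a low-rank FAMD reconstruction.
#' Missing continuous cells start at the column mean; the indicator
#' cells of a missing categorical value start at the observed level
#' proportions and stay fuzzy (continuous) across iterations, which
#' lets the observed variables drive the reconstruction instead of the
#' initial guess reinforcing itself. At each step the completed matrix
#' is rescaled (unit population variance for continuous columns, level
#' indicators divided by the square root of their current proportion and
#' centred), decomposed on `n_components` axes, and the missing cells
#' are refreshed from the reconstruction, until the largest change falls
#' below `tol` or `max_iter` is reached. On exit each fuzzy categorical
#' cell is committed to its highest-scoring observed level. The
#' procedure is deterministic.
#'
#' @param table Data frame with missing cells (fraction below 30%).
#' @param n_components Rank of the reconstruction (default 2).
#' @param tol Convergence tolerance on standardized cell changes
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 500; non-convergence warns and
#'   returns the last iterate).
#' @return The completed data frame.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, NA, 8))
#' impute_missing(d, n_components = 1)$y[3]   # 6, the rank-1 completion
#' @export
impute_missing <- function(table, n_components = 2, tol = 1e-8,
                           max_iter = 500L) {
  stopifnot(is.data.frame(table))
  if (!anyNA(table)) return(table)
  if (mean(is.na(table)) >= 0.3)
    stop("more than 30% missing cells")
  n <- nrow(table)
  is_num <- vapply(table, is.numeric, TRUE)

  # numeric working matrix: continuous columns then one indicator block
  # per categorical column (fuzzy cells allowed)
  blocks <- list()
  for (nm in names(table)) {
    x <- table[[nm]]
    if (all(is.na(x))) stop("column entirely missing: ", nm)
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      blocks[[nm]] <- list(type = "cont", x = x, miss = is.na(table[[nm]]))
    } else {
      f <- factor(x)
      lev <- levels(f)
      if (length(lev) < 2) stop("categorical column with a single level: ", nm)
      Z <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
      Z[cbind(seq_len(n), as.integer(f))] <- 1
      p_obs <- colSums(Z) / sum(!is.na(x))
      Z[is.na(x), ] <- rep(p_obs, each = sum(is.na(x)))
      blocks[[nm]] <- list(type = "cat", Z = Z, lev = lev,
                           miss = is.na(table[[nm]]))
    }
  }

  prev <- NULL
  for (it in seq_len(max_iter)) {
    Ms <- list(); scal <- list()
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      if (b$type == "cont") {
        mu <- mean(b$x)
        sig <- sqrt(mean((b$x - mu)^2))
        if (sig < 1e-12) sig <- 1
        Ms[[nm]] <- (b$x - mu) / sig
        scal[[nm]] <- list(mu = mu, sig = sig)
      } else {
        p <- pmax(colMeans(b$Z), 1e-9)
        Ms[[nm]] <- sweep(sweep(b$Z, 2, p), 2, sqrt(p), "/")
        scal[[nm]] <- list(p = p)
      }
    }
    M <- do.call(cbind, Ms) / sqrt(n)
    sv <- svd(M)
    k <- min(n_components, sum(sv$d > 1e-10))
    rec <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], k) %*%
      t(sv$v[, seq_len(k), drop = FALSE]) * sqrt(n)

    cur <- numeric(0)
    col0 <- 0L
    for (nm in names(blocks)) {
      b <- blocks[[nm]]
      if (b$type == "cont") {
        col0 <- col0 + 1L
        if (any(b$miss)) {
          sc <- scal[[nm]]
          blocks[[nm]]$x[b$miss] <- rec[b$miss, col0] * sc$sig + sc$mu
          cur <- c(cur, rec[b$miss, col0])
        }
      } else {
        cols <- col0 + seq_along(b$lev)
        col0 <- col0 + length(b$lev)
        if (any(b$miss)) {
          p <- scal[[nm]]$p
          zhat <- sweep(sweep(rec[b$miss, cols, drop = FALSE], 2,
                              sqrt(p), "*"), 2, p, "+")
          blocks[[nm]]$Z[b$miss, ] <- zhat
          cur <- c(cur, as.vector(zhat))
        }
      }
    }
    if (!is.null(prev) && max(abs(cur - prev)) < tol) break
    prev <- cur
    if (it == max_iter)
      warning("imputation did not converge in ", max_iter, " iterations")
  }

  filled <- table
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!any(b$miss)) next
    if (b$type == "cont") filled[[nm]][b$miss] <- b$x[b$miss]
    else {
      pick <- b$lev[apply(b$Z[b$miss, , drop = FALSE], 1, which.max)]
      if (is.factor(filled[[nm]]))
        filled[[nm]][b$miss] <- factor(pick, levels = levels(filled[[nm]]))
      else filled[[nm]][b$miss] <- pick
    }
  }
  filled
}
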