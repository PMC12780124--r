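#' Bin contact pairs into a symmetric genome-wide contact matrix
#'
#' Each fully mapped pair increments exactly one cell (i, j) with i <= j of
#' a symmetric matrix over genome-wide bins of fixed size; the diagonal is
#' allowed. Total matrix mass (upper triangle incl. diagonal) equals the
#' number of binned pairs.
#'
#' @param pairs Pair table (normally filtered at MAPQ >= 1 first, the
#'   conventional threshold for contact matrices).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (e.g. 2.5e6 or 5e4, the two standard
#'   presets).
#' @return A `contact_matrix`: list with `counts` (sparse symmetric
#'   `Matrix`), `bins` (`data.frame`: `bin` (1-based index), `chrom`,
#'   `start`, `end`), `bin_size`, `chrom_lengths`.
#' @export
bin_contacts <- function(pairs, chrom_lengths, bin_size) {
  bin_size <- as.numeric(bin_size)
  stopifnot(bin_size >= 1)
  chroms <- names(chrom_lengths)
  n_bins <- pmax(1L, as.integer(ceiling(as.numeric(chrom_lengths) / bin_size)))
  offset <- stats::setNames(cumsum(c(0L, n_bins[-length(n_bins)])), chroms)
  total_bins <- sum(n_bins)
  bins <- data.frame(
    bin = seq_len(total_bins),
    chrom = rep(chroms, n_bins),
    start = unlist(lapply(n_bins, function(k) (seq_len(k) - 1) * bin_size)),
    stringsAsFactors = FALSE
  )
  bins$end <- pmin(bins$start + bin_size,
                   as.numeric(chrom_lengths)[match(bins$chrom, chroms)])
  p <- pairs[!is.na(pairs$chrom1) & !is.na(pairs$chrom2), , drop = FALSE]
  if (nrow(p)) {
    if (!all(p$chrom1 %in% chroms) || !all(p$chrom2 %in% chroms))
      stop("pair chromosome absent from chrom_lengths")
    L1 <- as.numeric(chrom_lengths)[match(p$chrom1, chroms)]
    L2 <- as.numeric(chrom_lengths)[match(p$chrom2, chroms)]
    if (any(p$pos1 < 0 | p$pos1 >= L1 | p$pos2 < 0 | p$pos2 >= L2))
      stop("pair coordinate beyond chromosome length")
    i <- offset[p$chrom1] + floor(p$pos1 / bin_size) + 1
    j <- offset[p$chrom2] + floor(p$pos2 / bin_size) + 1
    ij <- cbind(pmin(i, j), pmax(i, j))
    counts <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                                   dims = c(total_bins, total_bins),
                                   symmetric = TRUE)
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0),
                                   dims = c(total_bins, total_bins),
                                   symmetric = TRUE)
  }
  structure(list(counts = counts, bins = bins, bin_size = bin_size,
                 chrom_lengths = chrom_lengths),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d bins at %s bp over %d chromosome(s); %s contacts\n",
    nrow(x$bins), format(x$bin_size, big.mark = ",", scientific = FALSE),
    length(x$chrom_lengths),
    format(matrix_total(x), big.mark = ",")))
  invisible(x)
}

#' Total contact count of a matrix
#'
#' Upper triangle plus diagonal, i.e. the number of pairs binned in.
#' @param m A `contact_matrix`.
#' @export
matrix_total <- function(m) {
  d <- as.matrix(m$counts)
  sum(d[upper.tri(d, diag = TRUE)])
}

.components <- function(adj) {
  # connected components of a logical adjacency matrix (BFS)
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Knight-Ruiz matrix balancing
#'
#' Computes the symmetric diagonal scaling `diag(w) %*% M %*% diag(w)` with
#' equal row sums via the Knight-Ruiz inner-outer Newton iteration
#' (conjugate-gradient inner solves). All-zero rows are masked before
#' balancing. If the unmasked submatrix is disconnected the balancing
#' problem is degenerate (weights are not unique — each component can be
#' rescaled freely — and the convergence theory assumes full
#' indecomposability), so the routine returns an explicit failure status
#' instead of arbitrary weights; likewise non-convergence within
#' `max_iter` outer iterations is flagged, never silently returned.
#'
#' @param m A `contact_matrix` or a base/`Matrix` symmetric non-negative
#'   matrix.
#' @param tol Relative row-sum tolerance (default 1e-6).
#' @param max_iter Maximum outer Newton iterations (default 100).
#' @return A `kr_weights` object: list with `weights` (per-bin weight, `NA`
#'   on masked bins), `converged` (logical), `status` (`"converged"`,
#'   `"disconnected"` or `"max_iter"`), `iterations`, `masked` (indices),
#'   `row_sum_dispersion` (max/min - 1 of unmasked balanced row sums).
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 100L) {
  A_full <- if (inherits(m, "contact_matrix")) as.matrix(m$counts)
            else as.matrix(m)
  if (!isSymmetric(unname(A_full), tol = 1e-8))
    stop("matrix must be symmetric")
  if (any(A_full < 0)) stop("matrix must be non-negative")
  n_full <- nrow(A_full)
  masked <- which(rowSums(A_full) == 0)
  keep <- setdiff(seq_len(n_full), masked)
  weights <- rep(NA_real_, n_full)
  result <- function(status, x = NULL, iters = 0L) {
    disp <- NA_real_
    if (!is.null(x)) {
      weights[keep] <<- x
      rs <- x * as.vector(A %*% x)
      disp <- max(rs) / min(rs) - 1
    }
    structure(list(weights = weights, converged = status == "converged",
                   status = status, iterations = iters, masked = masked,
                   row_sum_dispersion = disp),
              class = "kr_weights")
  }
  if (length(keep) == 0L) return(result("converged", iters = 0L))
  A <- A_full[keep, keep, drop = FALSE]
  # degenerate-input contract: several mutually non-interacting blocks make
  # the equal-row-sum problem decouple, so the common-value convention is
  # arbitrary per block; flag instead of returning weights. Isolated bins
  # whose only contact is their own diagonal are trivially balanced and do
  # not trigger this.
  off <- A > 0
  diag(off) <- FALSE
  comp <- .components(off | diag(nrow(A)) > 0)
  nontrivial <- sum(tabulate(comp) >= 2L)
  if (nontrivial >= 2L) return(result("disconnected"))
  n <- nrow(A)
  # Knight & Ruiz inner-outer Newton scheme, row sums scaled to 1
  Ah <- A / mean(rowSums(A))          # scale so x ~ O(1)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.2   # 2-norm residual bound; keeps row-sum spread < tol
  rt <- stop_tol^2
  v <- x * as.vector(Ah %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  i <- 0L
  while (rout > rt && i < max_iter) {
    i <- i + 1L
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- numeric(n)
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(Ah %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 2L * n) break
    }
    x <- x * y
    v <- x * as.vector(Ah %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # adaptive forcing term
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / (2 * res_norm + 1e-300))
  }
  if (rout > rt) return(result("max_iter", x = NULL, iters = i))
  # undo the mass rescaling so diag(x) A diag(x) has equal row sums (= 1)
  x <- x / sqrt(mean(rowSums(A)))
  res <- result("converged", x = x, iters = i)
  if (res$row_sum_dispersion > 10 * tol) res$status <- "max_iter"
  res$converged <- res$status == "converged"
  res
}

#' @export
print.kr_weights <- function(x, ...) {
  cat(sprintf("<kr_weights> status: %s (%d outer iterations), %d masked bin(s)\n",
              x$status, x$iterations, length(x$masked)))
  if (!is.na(x$row_sum_dispersion))
    cat(sprintf("  row-sum dispersion (max/min - 1): %.3g\n",
                x$row_sum_dispersion))
  invisible(x)
}

#' Balanced view of a contact matrix
#'
#' @param m A `contact_matrix`.
#' @param w A converged `kr_weights` for `m`.
#' @return Dense matrix `diag(w) %*% counts %*% diag(w)` with `NA` on
#'   masked bins.
#' @export
balanced_counts <- function(m, w) {
  stopifnot(inherits(m, "contact_matrix"), inherits(w, "kr_weights"))
  if (!w$converged) stop("balancing did not converge (status: ", w$status, ")")
  wt <- w$weights
  out <- as.matrix(m$counts) * outer(wt, wt)
  out
}

#' Squared Pearson correlation between two contact matrices
#'
#' Correlates cell values over the upper triangle (incl. diagonal) of two
#' matrices on identical binning; reports Pearson r and r². By default all
#' cells defined (non-masked) in both matrices enter, including zeros — the
#' conservative inclusion rule; `nonzero_only = TRUE` restricts to cells
#' nonzero in at least one matrix.
#'
#' @param m1,m2 `contact_matrix` objects with identical chromosomes and bin
#'   size.
#' @param w1,w2 Optional converged `kr_weights`; when both are supplied the
#'   balanced views are correlated and masked bins are excluded.
#' @param nonzero_only Restrict to cells nonzero in either matrix.
#' @return List with `r`, `r2`, `n_cells`.
#' @export
matrix_correlation <- function(m1, m2, w1 = NULL, w2 = NULL,
                               nonzero_only = FALSE) {
  if (!identical(names(m1$chrom_lengths), names(m2$chrom_lengths)) ||
      !isTRUE(all.equal(as.numeric(m1$chrom_lengths),
                        as.numeric(m2$chrom_lengths))) ||
      m1$bin_size != m2$bin_size)
    stop("matrices must share chromosomes and bin size")
  a <- as.matrix(m1$counts)
  b <- as.matrix(m2$counts)
  mask <- rep(FALSE, nrow(a))
  if (!is.null(w1) && !is.null(w2)) {
    a <- balanced_counts(m1, w1)
    b <- balanced_counts(m2, w2)
    mask <- is.na(w1$weights) | is.na(w2$weights)
  }
  ut <- upper.tri(a, diag = TRUE)
  ok <- ut & !outer(mask, mask, `|`)
  x <- a[ok]; y <- b[ok]
  if (nonzero_only) {
    nz <- x != 0 | y != 0
    x <- x[nz]; y <- y[nz]
  }
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2, n_cells = length(x))
}
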