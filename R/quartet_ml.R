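#' GTR+Gamma model parameters
#'
#' General time-reversible nucleotide model with optional discrete-Gamma
#' rate heterogeneity. The rate matrix is `Q[x,y] = s[x,y] * pi[y]` for
#' `x != y` with symmetric exchangeabilities `s`, rows summing to zero,
#' normalized so the expected substitution rate at stationarity is 1
#' (branch lengths are then expected substitutions per site).
#'
#' @param exchangeabilities six nonnegative rates in the order
#'   AC, AG, AT, CG, CT, GT; GT is conventionally fixed at 1 for
#'   identifiability. Default all 1.
#' @param base_freqs four frequencies (A, C, G, T) summing to 1.
#' @param gamma_shape Gamma shape `alpha`; `Inf` disables rate
#'   heterogeneity.
#' @param n_categories number of discrete Gamma categories (default 4).
#' @return an object of class `gtr_params`.
#' @export
gtr_params <- function(exchangeabilities = rep(1, 6),
                       base_freqs = rep(0.25, 4),
                       gamma_shape = Inf, n_categories = 4L) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities > 0),
            length(base_freqs) == 4L, all(base_freqs >= 0),
            abs(sum(base_freqs) - 1) < 1e-8,
            gamma_shape > 0, n_categories >= 1L)
  structure(list(
    exchangeabilities = as.numeric(exchangeabilities),
    base_freqs = as.numeric(base_freqs) / sum(base_freqs),
    gamma_shape = gamma_shape,
    n_categories = as.integer(n_categories)
  ), class = "gtr_params")
}

# Mean-per-category discretization of the Gamma(alpha, alpha) rate
# distribution (equal-probability categories, category value = conditional
# mean), normalized to mean exactly 1.
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L || !is.finite(alpha)) return(rep(1, k))
  b <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  p <- c(0, pgamma(b, shape = alpha + 1, rate = alpha), 1)
  r <- k * diff(p)
  r / mean(r)
}

# eigendecomposition of the normalized reversible Q via pi-symmetrization
# (real spectrum guaranteed); returns U, Uinv, lambda with Q = U L Uinv
gtr_eigen <- function(exch, pi) {
  pi <- pi / sum(pi)
  if (any(pi <= 0)) {             # guard degenerate empirical compositions
    pi <- pmax(pi, 1e-6)
    pi <- pi / sum(pi)
  }
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- exch[1]   # AC
  S[1, 3] <- S[3, 1] <- exch[2]   # AG
  S[1, 4] <- S[4, 1] <- exch[3]   # AT
  S[2, 3] <- S[3, 2] <- exch[4]   # CG
  S[2, 4] <- S[4, 2] <- exch[5]   # CT
  S[3, 4] <- S[4, 3] <- exch[6]   # GT
  Q <- S * rep(pi, each = 4)      # Q[x,y] = s[x,y] * pi[y]
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  d <- sqrt(pi)
  B <- (d %o% (1 / d)) * Q        # diag(d) Q diag(1/d), symmetric
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- e$vectors / d              # diag(1/d) V
  Uinv <- t(e$vectors) * rep(d, each = 4)
  list(U = U, Uinv = Uinv, lambda = e$values, pi = pi, Q = Q)
}

#' Site-pattern counts of a quartet block
#'
#' Collapses the columns of a 4-row micro-alignment to counts over the 256
#' ordered nucleotide 4-tuples — the sufficient statistic for the 4-leaf
#' likelihood. Rows are ordered by sorted taxon label.
#'
#' @param block a `pblock`.
#' @param columns `"all"` uses every column; `"dontcare"` uses only
#'   don't-care columns of the block's pattern (match columns are constant
#'   by construction).
#' @return a list with `states` (4 x npat matrix of codes 0..3), `counts`,
#'   `n_sites`, `taxa`, `freqs` (empirical base frequencies of the used
#'   columns).
#' @export
site_pattern_counts <- function(block, columns = c("all", "dontcare")) {
  columns <- match.arg(columns)
  stopifnot(inherits(block, "pblock"))
  aln <- block$alignment
  if (columns == "dontcare") {
    if (is.null(block$pattern))
      stop("dontcare column selection requires the block's pattern")
    aln <- aln[, block$pattern$mask == 0L, drop = FALSE]
  }
  pat_id <- aln[1, ] * 64L + aln[2, ] * 16L + aln[3, ] * 4L + aln[4, ] + 1L
  tab <- tabulate(pat_id, nbins = 256L)
  ids <- which(tab > 0L) - 1L
  states <- rbind(ids %/% 64L, (ids %/% 16L) %% 4L, (ids %/% 4L) %% 4L,
                  ids %% 4L)
  storage.mode(states) <- "integer"
  freqs <- tabulate(aln + 1L, nbins = 4L)
  list(states = states, counts = as.numeric(tab[tab > 0L]),
       n_sites = ncol(aln), taxa = block$taxa, freqs = freqs / sum(freqs))
}

# row orders putting the paired leaves first: split 1 = 12|34, 2 = 13|24,
# 3 = 14|23 (indices into the sorted-taxa rows)
.SPLIT_ORDERS <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
.SPLIT_NAMES <- c("12|34", "13|24", "14|23")

#' Quartet log-likelihood under GTR+Gamma
#'
#' Exact Felsenstein-pruning log-likelihood of an unrooted 4-leaf tree for
#' one of the three topologies, with a discrete-Gamma rate mixture.
#'
#' @param counts a [site_pattern_counts()] result.
#' @param split topology: 1/2/3 or `"12|34"`, `"13|24"`, `"14|23"` (pair
#'   indices refer to the rows of `counts`).
#' @param branch_lengths five nonnegative lengths: the four terminal
#'   branches in row order, then the internal branch.
#' @param params a [gtr_params()].
#' @return the log-likelihood.
#' @export
quartet_loglik <- function(counts, split, branch_lengths, params) {
  if (is.character(split)) split <- match(split, .SPLIT_NAMES)
  stopifnot(split %in% 1:3, length(branch_lengths) == 5L,
            all(is.finite(branch_lengths)), all(branch_lengths >= 0),
            inherits(params, "gtr_params"))
  eig <- gtr_eigen(params$exchangeabilities, params$base_freqs)
  rates <- discrete_gamma_rates(params$gamma_shape, params$n_categories)
  ord <- .SPLIT_ORDERS[[split]]
  quartet_loglik_cpp(counts$states[ord, , drop = FALSE], counts$counts,
                     c(branch_lengths[ord], branch_lengths[5L]),
                     eig$U, eig$Uinv, eig$lambda, eig$pi, rates)
}

#' Maximum-likelihood quartet topology of a P-block
#'
#' For each of the three unrooted topologies on the block's four taxa,
#' branch lengths (and the Gamma shape) are optimized by cyclic
#' coordinate-wise bounded maximization; the topology with the highest
#' optimized log-likelihood is selected. If the top two log-likelihoods
#' differ by no more than `tie_tol`, the block is flagged inconclusive.
#'
#' Base frequencies are the empirical frequencies of the used columns.
#' Under the default `params_policy = "fixed"` the exchangeabilities stay
#' at 1 (a 110-column block barely identifies five free rates);
#' `"gtr"` additionally optimizes the five free exchangeabilities.
#'
#' @param block a `pblock`.
#' @param params_policy `"fixed"` or `"gtr"`.
#' @param tie_tol log-likelihood gap (default `1e-3`) below which the
#'   block is inconclusive.
#' @param columns passed to [site_pattern_counts()].
#' @param n_categories discrete Gamma categories (default 4).
#' @param gamma optimize a Gamma shape (default `TRUE`); `FALSE` fixes
#'   rates homogeneous.
#' @return an object of class `quartet_result`: `taxa`, `logliks` (named
#'   by split), `best_split` (index 1..3 or `NA`), `split_taxa` (the four
#'   taxa ordered so the first two are siblings, or `NULL`),
#'   `inconclusive`, `alpha`, `branch_lengths`.
#' @export
best_topology <- function(block, params_policy = c("fixed", "gtr"),
                          tie_tol = 1e-3, columns = "all",
                          n_categories = 4L, gamma = TRUE) {
  params_policy <- match.arg(params_policy)
  counts <- site_pattern_counts(block, columns)
  fits <- lapply(1:3, function(s)
    fit_quartet_split(counts, s, params_policy, n_categories, gamma))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  names(ll) <- .SPLIT_NAMES
  converged <- vapply(fits, `[[`, logical(1), "converged")
  ord <- order(ll, decreasing = TRUE)
  gap <- ll[ord[1]] - ll[ord[2]]
  inconclusive <- gap <= tie_tol || !all(converged)
  if (!all(converged))
    warning("quartet optimizer failed to converge; block marked inconclusive")
  best <- if (inconclusive) NA_integer_ else ord[1]
  structure(list(
    taxa = counts$taxa,
    logliks = ll,
    best_split = best,
    split_taxa = if (!inconclusive) counts$taxa[.SPLIT_ORDERS[[best]]],
    inconclusive = inconclusive,
    alpha = if (!inconclusive) fits[[best]]$alpha,
    branch_lengths = if (!inconclusive) fits[[best]]$bl
  ), class = "quartet_result")
}

#' @export
print.quartet_result <- function(x, ...) {
  cat("<quartet_result>", paste(x$taxa, collapse = ", "), "\n")
  for (s in 1:3)
    cat(sprintf("  %s  logL = %.4f%s\n", .SPLIT_NAMES[s], x$logliks[s],
                if (identical(x$best_split, s)) "  *" else ""))
  if (x$inconclusive) cat("  inconclusive\n")
  invisible(x)
}

# Coordinate-descent ML fit of one topology. Branch lengths bounded in
# [1e-8, 10]; alpha in [0.02, 100] (log scale); exchangeabilities (gtr
# policy) in [1e-3, 1e3] (log scale). Start all branches at 0.05; on
# non-convergence retry from 0.5.
fit_quartet_split <- function(counts, split, policy, n_categories, gamma,
                              max_cycles = 25L, tol = 1e-6) {
  ord <- .SPLIT_ORDERS[[split]]
  states <- counts$states[ord, , drop = FALSE]
  cnt <- counts$counts
  freqs <- counts$freqs

  run <- function(start_bl) {
    bl <- rep(start_bl, 5)
    alpha <- 1
    exch <- rep(1, 6)
    eig <- gtr_eigen(exch, freqs)
    rates <- discrete_gamma_rates(if (gamma) alpha else Inf, n_categories)
    ll_of <- function(bl) quartet_loglik_cpp(states, cnt, bl, eig$U,
                                             eig$Uinv, eig$lambda, eig$pi,
                                             rates)
    ll <- ll_of(bl)
    converged <- FALSE
    for (cycle in seq_len(max_cycles)) {
      ll0 <- ll
      for (e in 1:5) {
        o <- optimize(function(x) { b <- bl; b[e] <- x; ll_of(b) },
                      c(1e-8, 10), maximum = TRUE, tol = 1e-6)
        if (o$objective > ll) { bl[e] <- o$maximum; ll <- o$objective }
      }
      if (gamma && n_categories > 1L) {
        o <- optimize(function(la) {
          r <- discrete_gamma_rates(exp(la), n_categories)
          quartet_loglik_cpp(states, cnt, bl, eig$U, eig$Uinv, eig$lambda,
                             eig$pi, r)
        }, log(c(0.02, 100)), maximum = TRUE, tol = 1e-4)
        if (o$objective > ll) {
          alpha <- exp(o$maximum)
          rates <- discrete_gamma_rates(alpha, n_categories)
          ll <- o$objective
        }
      }
      if (policy == "gtr") {
        for (e in 1:5) {      # GT (index 6) stays fixed at 1
          o <- optimize(function(lx) {
            ex <- exch; ex[e] <- exp(lx)
            eg <- gtr_eigen(ex, freqs)
            quartet_loglik_cpp(states, cnt, bl, eg$U, eg$Uinv, eg$lambda,
                               eg$pi, rates)
          }, log(c(1e-3, 1e3)), maximum = TRUE, tol = 1e-4)
          if (o$objective > ll) {
            exch[e] <- exp(o$maximum)
            eig <- gtr_eigen(exch, freqs)
            ll <- o$objective
          }
        }
      }
      if (ll - ll0 < tol) { converged <- TRUE; break }
    }
    list(loglik = ll, bl = bl[order(c(ord, 5L))], alpha = alpha,
         exch = exch, converged = converged)
  }

  fit <- run(0.05)
  if (!fit$converged) {
    fit2 <- run(0.5)
    if (fit2$converged || fit2$loglik > fit$loglik) fit <- fit2
  }
  fit
}
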