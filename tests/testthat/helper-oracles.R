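# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths for the quantity they check.

# --- naive spaced-word occurrence enumeration (string matching) -------------
# Returns a data.frame(taxon, strand, pos1, key) by sliding the mask with
# substring operations; windows with non-ACGT characters are skipped.
naive_occurrences <- function(seqs, mask_string, include_reverse = TRUE) {
  mask <- strsplit(mask_string, "")[[1]] == "1"
  l <- length(mask)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (tx in names(seqs)) {
    for (rec in seqs[[tx]]) {
      strands <- list(forward = rec)
      if (include_reverse) strands$reverse <- revcomp(rec)
      for (st in names(strands)) {
        s <- strands[[st]]
        n <- nchar(s)
        if (n < l) next
        for (i in seq_len(n - l + 1L)) {
          win <- substr(s, i, i + l - 1L)
          if (grepl("[^ACGT]", win)) next
          chars <- strsplit(win, "")[[1]]
          out[[length(out) + 1L]] <- data.frame(
            taxon = tx, strand = st, pos1 = i,
            key = paste(chars[mask], collapse = ""))
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(taxon = character(), strand = character(),
               pos1 = integer(), key = character())
}

# --- brute-force 4-leaf GTR+Gamma likelihood --------------------------------
# Sums over the 16 internal-state combinations per site and per rate
# category. Transition matrices come from ape::matexpo, the Q build and the
# Gamma discretization are written here from the textbook formulas.
oracle_gtr_Q <- function(exch, pi) {
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- c(exch[1], exch[2], exch[3], exch[4], exch[5], exch[6])
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * rowSums(S %*% diag(pi)))   # normalize mean rate to 1
}

oracle_gamma_rates <- function(alpha, k) {
  if (!is.finite(alpha) || k == 1) return(rep(1, k))
  q <- qgamma((1:(k - 1)) / k, alpha, alpha)
  p <- c(0, pgamma(q, alpha + 1, alpha), 1)
  r <- k * diff(p)
  r / mean(r)
}

# states: 4 x nsite integer (0..3), leaves 1,2 join node u; 3,4 join node v.
oracle_quartet_loglik <- function(states, counts, bl, exch, pi, alpha = Inf,
                                  ncat = 1L, root = c("u", "v")) {
  root <- match.arg(root)
  Q <- oracle_gtr_Q(exch, pi)
  rates <- oracle_gamma_rates(alpha, ncat)
  ll <- 0
  for (p in seq_len(ncol(states))) {
    s <- states[, p] + 1L
    site <- 0
    for (r in rates) {
      P <- lapply(bl, function(t) ape::matexpo(Q * (t * r)))
      acc <- 0
      for (x in 1:4) for (y in 1:4) {
        p5 <- if (root == "u") P[[5]][x, y] else P[[5]][y, x]
        term <- P[[1]][x, s[1]] * P[[2]][x, s[2]] *
          P[[3]][y, s[3]] * P[[4]][y, s[4]] * p5
        acc <- acc + (if (root == "u") pi[x] else pi[y]) * term
      }
      site <- site + acc / length(rates)
    }
    ll <- ll + counts[p] * log(site)
  }
  ll
}

# --- tree utilities ---------------------------------------------------------
# induced quartet topologies of a tree via the four-point condition on
# cophenetic distances (independent of the package's bipartition code)
quartets_of_tree <- function(tr) {
  D <- ape::cophenetic.phylo(tr)
  taxa <- tr$tip.label
  qs <- t(combn(taxa, 4))
  t(apply(qs, 1, function(x) {
    s <- c(D[x[1], x[2]] + D[x[3], x[4]],
           D[x[1], x[3]] + D[x[2], x[4]],
           D[x[1], x[4]] + D[x[2], x[3]])
    k <- which.min(s)
    if (k == 1) x else if (k == 2) x[c(1, 3, 2, 4)] else x[c(1, 4, 2, 3)]
  }))
}

# brute-force RF: symmetric difference of bipartition sets extracted with
# ape::prop.part on rooted copies (a code path disjoint from rf_distance)
oracle_rf <- function(t1, t2) {
  parts <- function(tr) {
    tr <- ape::unroot(tr)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    n <- length(labs)
    keys <- vapply(pp, function(i) {
      side <- sort(labs[i])
      if (length(side) <= 1L || length(side) >= n - 1L) return(NA_character_)
      ref <- sort(labs)[1]                  # canonical: side without min label
      if (ref %in% side) side <- sort(setdiff(labs, side))
      paste(side, collapse = "|")
    }, character(1))
    unique(keys[!is.na(keys)])
  }
  b1 <- parts(t1); b2 <- parts(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
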