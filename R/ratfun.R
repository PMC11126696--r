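# Rational functions: quotients of two mp polynomials, used as the scalar
# field for exact linear algebra (determining-system nullspace, structure
# constants, adjoint matrices).  Only scalar and monomial content is
# cancelled; full multivariate gcd is unnecessary at the sizes arising here.

rf <- function(num, den = mp_one()) {
  if (mp_is_zero(den)) stop("rational function with zero denominator")
  structure(rf_normalize_raw(list(num = num, den = den)), class = "rf")
}

rf_zero <- function() rf(mp_zero())
rf_one <- function() rf(mp_one())
rf_const <- function(num, den = 1) rf(mp_const(num, den))
rf_from_mp <- function(p) rf(p)
rf_is_zero <- function(x) mp_is_zero(x$num)

# factor out the common monomial and the scalar content shared by numerator
# and denominator; fix the sign of the leading denominator coefficient
rf_normalize_raw <- function(x) {
  num <- x$num; den <- x$den
  if (mp_is_zero(num)) return(list(num = num, den = mp_one()))
  al <- mp_align(num, den)
  if (length(al$vars)) {
    common <- pmin(apply(al$pe, 2, min), apply(al$qe, 2, min))
    if (any(common != 0L)) {
      num <- mp_make(sweep(al$pe, 2, common), num$num, num$den)
      den <- mp_make(sweep(al$qe, 2, common), den$num, den$den)
    }
  }
  # scalar: make both integer-coefficient and primitive, track the ratio
  scal <- function(p) {
    l <- Reduce(function(a, b) a / rat_gcd(a, b) * b, p$den, 1)  # lcm of dens
    ints <- p$num * (l / p$den)
    g <- Reduce(rat_gcd, abs(ints))
    list(p = mp_make(p$exp, ints / g, rep(1, length(ints))), c_num = g, c_den = l)
  }
  sn <- scal(num); sd <- scal(den)
  num <- sn$p; den <- sd$p
  # overall scalar sn$c_num/sn$c_den / (sd$c_num/sd$c_den) applied to num
  r <- rat_mul2(sn$c_num, sn$c_den, sd$c_den, sd$c_num)
  num <- mp_scale(num, r$num, r$den)
  if (den$num[nrow(den$exp)] < 0) { den <- mp_neg(den); num <- mp_neg(num) }
  list(num = num, den = den)
}

rf_add <- function(x, y) {
  if (rf_is_zero(x)) return(y)
  if (rf_is_zero(y)) return(x)
  if (mp_equal(x$den, y$den)) return(rf(mp_add(x$num, y$num), x$den))
  rf(mp_add(mp_mul(x$num, y$den), mp_mul(y$num, x$den)), mp_mul(x$den, y$den))
}

rf_neg <- function(x) { x$num <- mp_neg(x$num); x }
rf_sub <- function(x, y) rf_add(x, rf_neg(y))
rf_mul <- function(x, y) {
  if (rf_is_zero(x) || rf_is_zero(y)) return(rf_zero())
  rf(mp_mul(x$num, y$num), mp_mul(x$den, y$den))
}
rf_div <- function(x, y) {
  if (rf_is_zero(y)) stop("division by zero rational function")
  rf(mp_mul(x$num, y$den), mp_mul(x$den, y$num))
}
rf_equal <- function(x, y) rf_is_zero(rf_sub(x, y))
rf_eval <- function(x, vals) mp_eval(x$num, vals) / mp_eval(x$den, vals)
rf_format <- function(x) {
  if (rf_is_zero(x)) return("0")
  n <- mp_format(x$num)
  if (mp_equal(x$den, mp_one())) return(n)
  paste0("(", n, ")/(", mp_format(x$den), ")")
}

#' @export
print.rf <- function(x, ...) { cat(rf_format(x), "\n"); invisible(x) }

## ---- linear algebra over rational functions ----

# matrices are plain R lists of lists (rows of rf scalars)
rf_matrix <- function(nrow, ncol) {
  lapply(seq_len(nrow), function(i) lapply(seq_len(ncol), function(j) rf_zero()))
}

# Gauss-Jordan reduction; returns list(rref, pivots)
rf_rref <- function(M) {
  nr <- length(M)
  nc <- if (nr) length(M[[1]]) else 0L
  pivots <- integer(0)
  r <- 1L
  for (c in seq_len(nc)) {
    if (r > nr) break
    # pick the structurally simplest nonzero pivot in column c at rows >= r
    cand <- Filter(function(i) !rf_is_zero(M[[i]][[c]]), seq(r, nr))
    if (!length(cand)) next
    size <- vapply(cand, function(i)
      nrow(M[[i]][[c]]$num$exp) + nrow(M[[i]][[c]]$den$exp), numeric(1))
    p <- cand[which.min(size)]
    if (p != r) { tmp <- M[[p]]; M[[p]] <- M[[r]]; M[[r]] <- tmp }
    piv <- M[[r]][[c]]
    M[[r]] <- lapply(M[[r]], function(x) rf_div(x, piv))
    for (i in seq_len(nr)) {
      if (i == r) next
      f <- M[[i]][[c]]
      if (rf_is_zero(f)) next
      M[[i]] <- mapply(function(a, b) rf_sub(a, rf_mul(f, b)),
                       M[[i]], M[[r]], SIMPLIFY = FALSE)
    }
    pivots <- c(pivots, c)
    r <- r + 1L
  }
  list(rref = M, pivots = pivots)
}

# nullspace basis of M x = 0; returns list of coefficient vectors (lists of rf)
rf_nullspace <- function(M, ncol) {
  if (!length(M)) {
    return(lapply(seq_len(ncol), function(j) {
      v <- rep(list(rf_zero()), ncol); v[[j]] <- rf_one(); v
    }))
  }
  rr <- rf_rref(M)
  pivots <- rr$pivots
  free <- setdiff(seq_len(ncol), pivots)
  lapply(free, function(f) {
    v <- rep(list(rf_zero()), ncol)
    v[[f]] <- rf_one()
    for (k in seq_along(pivots)) {
      v[[pivots[k]]] <- rf_neg(rr$rref[[k]][[f]])
    }
    v
  })
}

# solve M x = b exactly (unique-solution or least structured); returns NULL if
# inconsistent.  M: list rows of rf; b: list of rf.
rf_solve <- function(M, b) {
  nr <- length(M); nc <- if (nr) length(M[[1]]) else 0L
  aug <- lapply(seq_len(nr), function(i) c(M[[i]], list(b[[i]])))
  rr <- rf_rref(aug)
  piv <- rr$pivots
  if ((nc + 1L) %in% piv) return(NULL)  # inconsistent
  x <- rep(list(rf_zero()), nc)
  for (k in seq_along(piv)) x[[piv[k]]] <- rr$rref[[k]][[nc + 1L]]
  x
}
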