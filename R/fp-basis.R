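#' Fractional-polynomial power set
#'
#' The standard Royston-Altman power set used for fractional-polynomial
#' regression bases. Power 0 denotes the natural logarithm.
#'
#' @return Numeric vector of the eight admissible powers.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Construct a fractional-polynomial specification
#'
#' An FP specification is an ordered tuple of one or two powers drawn from
#' [fp_powers()]. Ages are always expressed in years; transforms are defined
#' only for positive age. A repeated power `p` denotes the basis
#' `(age^p, age^p * log(age))`.
#'
#' @param powers numeric vector of length 1 or 2, each in [fp_powers()];
#'   for two powers they must be in non-decreasing order.
#' @return An object of class `fp_spec`.
#' @export
fp_spec <- function(powers) {
  powers <- as.numeric(powers)
  if (!length(powers) %in% c(1L, 2L))
    stop("an FP specification has 1 or 2 powers", call. = FALSE)
  if (!all(powers %in% fp_powers()))
    stop("all powers must belong to the standard power set {",
         paste(fp_powers(), collapse = ", "), "}", call. = FALSE)
  if (length(powers) == 2L && powers[1] > powers[2])
    stop("powers must be in non-decreasing order (canonical form)", call. = FALSE)
  structure(list(powers = powers, age_unit = "years"), class = "fp_spec")
}

#' @export
print.fp_spec <- function(x, ...) {
  cat("FP", length(x$powers), " basis, powers (",
      paste(x$powers, collapse = ", "), "), age in years\n", sep = "")
  invisible(x)
}

#' @export
format.fp_spec <- function(x, ...) paste0("(", paste(x$powers, collapse = ","), ")")

as_fp_spec <- function(x) if (inherits(x, "fp_spec")) x else fp_spec(x)

# single-power transform: x^p with x^0 = log(x)
fp_term <- function(age, p) if (p == 0) log(age) else age^p

#' Evaluate a fractional-polynomial basis
#'
#' Returns the basis values (one column per basis term, without intercept)
#' for positive ages. For distinct powers (p1, p2) the basis is
#' `(age^p1, age^p2)` with `age^0 = log(age)`; for a repeated power p it is
#' `(age^p, age^p * log(age))`; for a single power just `(age^p)`.
#'
#' @param age positive numeric vector, age in years.
#' @param spec an [fp_spec()] (or a numeric power vector coerced to one).
#' @return Numeric matrix with `length(age)` rows and one column per term.
#' @export
fp_transform <- function(age, spec) {
  spec <- as_fp_spec(spec)
  age <- as.numeric(age)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive and finite (years)", call. = FALSE)
  p <- spec$powers
  if (length(p) == 1L) {
    m <- cbind(fp_term(age, p))
    colnames(m) <- fp_term_names(spec)
    return(m)
  }
  if (p[1] == p[2]) {
    b1 <- fp_term(age, p[1])
    m <- cbind(b1, b1 * log(age))
  } else {
    m <- cbind(fp_term(age, p[1]), fp_term(age, p[2]))
  }
  colnames(m) <- fp_term_names(spec)
  m
}

fp_term_names <- function(spec) {
  p <- spec$powers
  nm <- function(p) if (p == 0) "log(age)" else paste0("age^", p)
  if (length(p) == 1L) return(nm(p[1]))
  if (p[1] == p[2]) c(nm(p[1]), paste0(nm(p[1]), ".log(age)"))
  else c(nm(p[1]), nm(p[2]))
}

# derivative of a single basis term at age a:
#   d/da a^p = p a^(p-1);  d/da log a = 1/a;  d/da a^p log a = a^(p-1)(p log a + 1);
#   repeated power 0 has second term (log a)^2 with derivative 2 log(a)/a
fp_term_deriv <- function(age, p, with_log = FALSE) {
  if (with_log) {
    if (p == 0) return(2 * log(age) / age)
    return(age^(p - 1) * (p * log(age) + 1))
  }
  if (p == 0) 1 / age else p * age^(p - 1)
}

#' Analytic derivative of a fractional-polynomial curve
#'
#' Computes `d/d age` of `sum_k coeffs[k] * basis_k(age)` for the basis
#' defined by `spec`. The intercept contributes zero and is not passed.
#'
#' @param age positive numeric vector (years).
#' @param spec an [fp_spec()].
#' @param coeffs numeric vector, one coefficient per basis term.
#' @return Numeric vector of derivatives (volume units per year).
#' @export
fp_derivative <- function(age, spec, coeffs) {
  spec <- as_fp_spec(spec)
  age <- as.numeric(age)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive and finite (years)", call. = FALSE)
  p <- spec$powers
  if (length(coeffs) != length(p))
    stop("need exactly one coefficient per basis term", call. = FALSE)
  if (length(p) == 1L) return(coeffs[1] * fp_term_deriv(age, p[1]))
  if (p[1] == p[2]) {
    coeffs[1] * fp_term_deriv(age, p[1]) +
      coeffs[2] * fp_term_deriv(age, p[1], with_log = TRUE)
  } else {
    coeffs[1] * fp_term_deriv(age, p[1]) + coeffs[2] * fp_term_deriv(age, p[2])
  }
}

#' Enumerate all second-order fractional-polynomial candidates
#'
#' All canonical FP2 specifications over the standard power set: the 28
#' distinct pairs plus the 8 repeated pairs, 36 in all, in lexicographic
#' order of (p1, p2). Includes the conventional quadratic (1, 2).
#'
#' @return List of 36 [fp_spec()] objects.
#' @export
fp2_candidates <- function() {
  S <- fp_powers()
  out <- list()
  for (i in seq_along(S)) for (j in i:length(S))
    out[[length(out) + 1L]] <- fp_spec(c(S[i], S[j]))
  out
}
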