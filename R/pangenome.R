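# Pan/core rarefaction over random genome-addition orders, Heaps'-law
# power-law fit for the pan-genome, exponential decay fit for the core
# genome, and the openness classification.

#' Pan- and core-genome rarefaction curves
#'
#' For each of `n_permutations` random genome orders and each prefix length
#' n, counts the pan-genome size (families present in >= 1 of the first n
#' genomes) and core size (families present in all of them); medians across
#' permutations are reported per n, following the standard
#' random-permutation protocol.
#'
#' @param pan_matrix Families x genomes count matrix.
#' @param n_permutations Number of random genome orders (default 100).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all `N!` genome orders instead of sampling
#'   (only allowed for <= 8 genomes); makes the medians exact.
#' @return A tibble of class `rarefaction_series`: `n`, `pan_median`,
#'   `core_median`; attributes `n_permutations` and `seed`.
#' @export
rarefaction_curves <- function(pan_matrix, n_permutations = 100, seed = 1L,
                               exhaustive = FALSE) {
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  if (ncol(pan_matrix) < 2) abort("need >= 2 genomes")
  pres <- pan_matrix >= 1
  N <- ncol(pres)
  if (exhaustive) {
    if (N > 8) abort("exhaustive enumeration is limited to 8 genomes")
    perms <- .all_perms(N)
    n_permutations <- nrow(perms)
  }
  set.seed(seed)
  pan <- core <- matrix(0, n_permutations, N)
  for (p in seq_len(n_permutations)) {
    ord <- if (exhaustive) perms[p, ] else sample.int(N)
    m <- pres[, ord, drop = FALSE]
    cum_any <- t(apply(m, 1, cummax))
    cum_all <- t(apply(m, 1, cummin))
    pan[p, ] <- colSums(cum_any)
    core[p, ] <- colSums(cum_all)
  }
  out <- tibble(n = seq_len(N),
                pan_median = apply(pan, 2, stats::median),
                core_median = apply(core, 2, stats::median))
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_series", class(out))
  out
}

# all permutations of 1..n (n small), one per row
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

.series_cols <- function(series, what = c("pan", "core")) {
  what <- match.arg(what)
  col <- paste0(what, "_median")
  if (!col %in% names(series)) {
    # allow plain (n, size) tables too
    col <- setdiff(names(series), "n")[1]
  }
  list(n = series$n, y = series[[col]])
}

#' Heaps'-law power-law fit of the pan-genome curve
#'
#' Fits `Ps(n) = kappa * n^gamma` by ordinary least squares on the log-log
#' scale (`log Ps = log kappa + gamma log n`), which is exact on noiseless
#' power-law data and deterministic.
#'
#' @param series A [rarefaction_curves()] result, or any tibble with columns
#'   `n` and `pan_median`.
#' @return An object of class `power_law_fit`: `kappa`, `gamma`, `rss` (on
#'   the raw scale), `n_points`, `data`.
#' @export
fit_power_law <- function(series) {
  d <- .series_cols(series, "pan")
  if (length(d$n) < 2) abort("need >= 2 points")
  if (any(d$y <= 0)) abort("pan-genome sizes must be positive for a power-law fit")
  fit <- stats::lm(log(d$y) ~ log(d$n))
  kappa <- exp(unname(coef(fit)[1]))
  gamma <- unname(coef(fit)[2])
  pred <- kappa * d$n^gamma
  structure(list(kappa = kappa, gamma = gamma,
                 rss = sum((d$y - pred)^2), n_points = length(d$n),
                 data = tibble(n = d$n, size = d$y, fitted = pred)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Heaps'-law fit: Ps(n) = %.2f * n^%.5f  (RSS %.4g, %d points) -> %s pan-genome\n",
              x$kappa, x$gamma, x$rss, x$n_points, classify_openness(x)))
  invisible(x)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("kappa", "gamma"), estimate = c(x$kappa, x$gamma))
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(kappa = x$kappa, gamma = x$gamma, rss = x$rss,
         n_points = x$n_points, openness = classify_openness(x))
}

# Residual sum of squares of the exponential model.
.exp_rss <- function(par, n, y, with_offset) {
  kc <- exp(par[1]); d <- par[2]
  om <- if (with_offset) par[3] else 0
  sum((y - (kc * exp(-d * n) + om))^2)
}

#' Exponential fit of the core-genome curve
#'
#' Fits `Fc(n) = kappa_c * exp(-decay * n) + Omega` (the offset `Omega` only
#' when `with_offset = TRUE`) by nonlinear least squares. Three documented
#' starts are tried — (i) log-linear regression of `log(Fc - Omega0)` on n,
#' (ii) a two-point slope from the first and last points, (iii) a flat-decay
#' start from the maximum — each polished by Nelder-Mead then BFGS
#' (relative tolerance 1e-12); the best RSS wins. On noiseless
#' two-parameter data start (i) is already exact.
#'
#' @param series A [rarefaction_curves()] result or tibble with `n` and
#'   `core_median` columns.
#' @param with_offset Fit the three-parameter form with asymptote `Omega`.
#' @return An object of class `core_exponential_fit`: `kappa_c`, `decay`
#'   (`= 1/tau_c`), `omega` (0 in the two-parameter form), `rss`,
#'   `n_points`, `data`.
#' @export
fit_core_exponential <- function(series, with_offset = FALSE) {
  d <- .series_cols(series, "core")
  n <- d$n; y <- d$y
  need <- if (with_offset) 4 else 3
  if (length(n) < need) abort(sprintf("need >= %d points", need))
  if (any(y <= 0)) abort("core sizes must be positive")

  if (max(y) - min(y) < 1e-12) {
    # constant series: the decay is unidentifiable; report the flat solution
    kc <- if (with_offset) 0 else y[1]
    om <- if (with_offset) y[1] else 0
    return(structure(list(kappa_c = kc, decay = 0, omega = om, rss = 0,
                          n_points = length(n),
                          data = tibble(n = n, size = y, fitted = y)),
                     class = "core_exponential_fit"))
  }

  om0 <- if (with_offset) max(0, min(y) * 0.9) else 0
  starts <- list()
  # (i) log-linear on (y - om0)
  ypos <- pmax(y - om0, max(y) * 1e-6)
  ll <- stats::lm(log(ypos) ~ n)
  starts[[1]] <- c(log(exp(unname(coef(ll)[1]))), max(-unname(coef(ll)[2]), 1e-8))
  # (ii) two-point slope first/last
  sl <- (log(ypos[length(ypos)]) - log(ypos[1])) / (n[length(n)] - n[1])
  starts[[2]] <- c(log(ypos[1]) + max(-sl, 1e-8) * n[1], max(-sl, 1e-8))
  # (iii) flat start from the maximum
  starts[[3]] <- c(log(max(y)), 1e-3)
  if (with_offset) starts <- lapply(starts, function(s) c(s, om0))

  best <- NULL
  for (s in starts) {
    o1 <- tryCatch(stats::optim(s, .exp_rss, n = n, y = y,
                                with_offset = with_offset,
                                method = "Nelder-Mead",
                                control = list(maxit = 2000, reltol = 1e-12)),
                   error = function(e) NULL)
    p <- if (!is.null(o1)) o1$par else s
    o2 <- tryCatch(stats::optim(p, .exp_rss, n = n, y = y,
                                with_offset = with_offset, method = "BFGS",
                                control = list(maxit = 1000, reltol = 1e-14)),
                   error = function(e) o1)
    cand <- if (!is.null(o2)) o2 else o1
    if (is.null(cand)) next
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best)) abort("exponential fit failed to converge from all starts")
  kc <- exp(best$par[1]); decay <- best$par[2]
  om <- if (with_offset) best$par[3] else 0
  pred <- kc * exp(-decay * n) + om
  structure(list(kappa_c = kc, decay = decay, omega = om,
                 rss = sum((y - pred)^2), n_points = length(n),
                 data = tibble(n = n, size = y, fitted = pred)),
            class = "core_exponential_fit")
}

#' @export
print.core_exponential_fit <- function(x, ...) {
  if (x$omega != 0) {
    cat(sprintf("Core-genome fit: Fc(n) = %.2f * exp(-%.6f n) + %.2f  (RSS %.4g)\n",
                x$kappa_c, x$decay, x$omega, x$rss))
  } else {
    cat(sprintf("Core-genome fit: Fc(n) = %.2f * exp(-%.6f n)  (RSS %.4g)\n",
                x$kappa_c, x$decay, x$rss))
  }
  invisible(x)
}

#' @method tidy core_exponential_fit
#' @export
tidy.core_exponential_fit <- function(x, ...) {
  tibble(term = c("kappa_c", "decay", "omega"),
         estimate = c(x$kappa_c, x$decay, x$omega))
}

#' @method glance core_exponential_fit
#' @export
glance.core_exponential_fit <- function(x, ...) {
  tibble(kappa_c = x$kappa_c, decay = x$decay, omega = x$omega,
         rss = x$rss, n_points = x$n_points)
}

#' Heaps'-law openness classification
#'
#' Under Heaps' law an exponent `0 < gamma < 1` means the pan-genome keeps
#' growing without bound as genomes are added ("open"); `gamma < 0` means it
#' is bounded ("closed"). Boundary values (`gamma = 0` or `gamma >= 1`) are
#' reported as `"indeterminate"` rather than silently assigned.
#'
#' @param power_fit A [fit_power_law()] result (or a number, the exponent).
#' @return `"open"`, `"closed"`, or `"indeterminate"`.
#' @export
classify_openness <- function(power_fit) {
  g <- if (inherits(power_fit, "power_law_fit")) power_fit$gamma else power_fit
  if (g > 0 && g < 1) "open" else if (g < 0) "closed" else "indeterminate"
}
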