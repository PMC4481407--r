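# Maximum-likelihood estimation of the heterochromatin fusigenicity weight w.
#
# The fitted model predicts the expected fraction of fused telomeres per
# category as a function of w. Two variants are available:
#   * "generative": the exact expected category frequencies of the simulator
#     (sequential weighted pairing without replacement, Poisson event counts),
#     computed by dynamic programming over the multiset of free telomeres.
#     This is the default: at several fusions per cell the sequential
#     depletion of heterochromatic telomeres is strong enough to bias a
#     single-draw likelihood noticeably.
#   * "single_event": each fusion treated as an independent draw from the full
#     pair space (probability proportional to w_i * w_j), ignoring depletion.
#     Cheap closed form; adequate when fusions per cell are rare.
# Category counts are treated as multinomial draws from the model frequencies
# (a composite likelihood: the two endpoints of one fusion are not strictly
# independent), and the bootstrap resamples fused telomeres accordingly.

# Collapse a karyotype into telomere types for the DP: one type per
# (category, heterochromatin-class) combination.
.bias_types <- function(karyotype) {
  tel <- karyotype$telomeres
  het <- tel$chromatin_class == "heterochromatin"
  key <- paste(tel$category, het)
  ord <- !duplicated(key)
  data.frame(
    category = tel$category[ord],
    het = het[ord],
    count = as.integer(table(key)[key[ord]]),
    stringsAsFactors = FALSE
  )
}

# Expected FT category frequencies under the generative model at weight w.
# `mean_events = NULL` gives the single-event (no depletion) frequencies.
.expected_category_freq <- function(types, w, mean_events = NULL,
                                    categories = NULL) {
  nt <- nrow(types)
  wts <- ifelse(types$het, w, 1)
  if (is.null(categories)) {
    categories <- unique(types$category)
  }
  cat_idx <- match(types$category, categories)
  total <- sum(types$count)
  kmax <- if (is.null(mean_events)) 1L else floor(total / 2)

  # pair types t <= u, with per-category endpoint contributions
  pid <- which(upper.tri(matrix(0, nt, nt), diag = TRUE), arr.ind = TRUE)
  tt <- pid[, 1]
  uu <- pid[, 2]
  wpair <- wts[tt] * wts[uu]
  M <- length(tt)
  Cmat <- matrix(0, M, length(categories))
  for (m in seq_len(M)) {
    Cmat[m, cat_idx[tt[m]]] <- Cmat[m, cat_idx[tt[m]]] + 1
    Cmat[m, cat_idx[uu[m]]] <- Cmat[m, cat_idx[uu[m]]] + 1
  }

  cnt <- matrix(types$count, nrow = 1)
  pstate <- 1
  ftexp <- numeric(length(categories))
  for (k in seq_len(kmax)) {
    pk <- if (is.null(mean_events)) 1 else
      stats::ppois(k - 1, mean_events, lower.tail = FALSE)
    if (pk < 1e-14) break
    np <- cnt[, tt, drop = FALSE] * cnt[, uu, drop = FALSE]
    diagm <- tt == uu
    if (any(diagm)) {
      np[, diagm] <- cnt[, tt[diagm], drop = FALSE] *
        (cnt[, tt[diagm], drop = FALSE] - 1) / 2
    }
    W <- sweep(np, 2, wpair, "*")
    P <- W / rowSums(W)
    # expected endpoints of event k, averaged over states
    ev_pair <- as.vector(crossprod(pstate, P)) # length M
    ftexp <- ftexp + pk * as.vector(crossprod(Cmat, ev_pair))
    if (k == kmax) break
    # transitions: state x pair-type
    ns <- nrow(cnt)
    probv <- as.vector(P * pstate) # column-major: states within pair-type
    newcnt <- cnt[rep(seq_len(ns), times = M), , drop = FALSE]
    rows_t <- cbind(seq_len(ns * M), rep(tt, each = ns))
    rows_u <- cbind(seq_len(ns * M), rep(uu, each = ns))
    newcnt[rows_t] <- newcnt[rows_t] - 1L
    newcnt[rows_u] <- newcnt[rows_u] - 1L
    ok <- probv > 0
    newcnt <- newcnt[ok, , drop = FALSE]
    probv <- probv[ok]
    keys <- do.call(paste, c(as.data.frame(newcnt), sep = ","))
    agg <- rowsum(probv, keys)
    first <- match(rownames(agg), keys)
    cnt <- newcnt[first, , drop = FALSE]
    pstate <- as.vector(agg)
  }
  stats::setNames(ftexp / sum(ftexp), categories)
}

# Grid of model frequencies over log-spaced w values, cached per
# (karyotype, method, mean) since it does not depend on the data.
.bias_cache <- new.env(parent = emptyenv())

.bias_grid <- function(karyotype, method, mean_events, w_cap, grid_size) {
  types <- .bias_types(karyotype)
  categories <- .karyotype_categories(karyotype)
  key <- paste(
    paste(types$category, types$het, types$count, collapse = ";"),
    method,
    if (is.null(mean_events)) "NULL" else format(mean_events, digits = 12),
    format(w_cap, digits = 12), grid_size,
    sep = "|"
  )
  hit <- .bias_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  logw <- seq(log(1e-6), log(w_cap), length.out = grid_size)
  me <- if (method == "generative") mean_events else NULL
  Q <- vapply(exp(logw), function(w) {
    .expected_category_freq(types, w, mean_events = me,
      categories = categories)
  }, numeric(length(categories)))
  out <- list(logw = logw, logQ = log(t(Q)), categories = categories)
  .bias_cache[[key]] <- out
  out
}

# Argmax over the grid with 3-point parabolic refinement in log w.
# LL: grid_size x n matrix of log-likelihood profiles.
.grid_argmax <- function(logw, LL) {
  G <- length(logw)
  h <- logw[2] - logw[1]
  idx <- max.col(t(LL), ties.method = "first")
  at_edge <- idx == 1L | idx == G
  ii <- pmin(pmax(idx, 2L), G - 1L)
  n <- ncol(LL)
  lm1 <- LL[cbind(ii - 1L, seq_len(n))]
  l0 <- LL[cbind(ii, seq_len(n))]
  lp1 <- LL[cbind(ii + 1L, seq_len(n))]
  denom <- lm1 - 2 * l0 + lp1
  shift <- ifelse(denom < 0, 0.5 * h * (lm1 - lp1) / denom, 0)
  shift <- pmin(pmax(shift, -h / 2), h / 2)
  out <- logw[ii] + shift
  out[at_edge] <- logw[idx[at_edge]]
  list(logw_hat = out, at_upper_edge = idx == G, at_lower_edge = idx == 1L)
}

#' Estimate the heterochromatin fusigenicity weight
#'
#' Maximum-likelihood estimate of the weight `w` by which
#' heterochromatin-class telomeres out-fuse the rest, from a per-category FT
#' count table. The fitted expected frequencies are, by default, those of the
#' full generative model (sequential weighted pairing with depletion and a
#' Poisson number of events per cell); `method = "single_event"` fits the
#' simpler independent-draw pair model. Confidence intervals are percentile
#' bootstrap over resampled fused telomeres.
#'
#' @param counts a [count_table()] (or named count vector) over the
#'   karyotype's categories with positive total.
#' @param karyotype the `karyotype` the counts refer to.
#' @param events_per_cell_mean Poisson mean used by the generative model;
#'   defaults to `n_TFs / n_cells` from `counts` when available, otherwise
#'   the method falls back to `"single_event"`.
#' @param method `"generative"` (default) or `"single_event"`.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the interval).
#' @param conf_level bootstrap interval coverage (default 0.95).
#' @param seed optional seed for the bootstrap.
#' @param w_cap upper bound on `w`; estimates at the cap (all information in
#'   one group) are flagged `capped`.
#' @param grid_size number of log-spaced grid points on `[1e-6, w_cap]` used
#'   to profile the likelihood before parabolic refinement.
#' @return A `bias_estimate` object: `w_hat`, `log_likelihood`, `ci_low`,
#'   `ci_high`, `converged`, `capped`, `method`, `events_per_cell_mean`,
#'   `n_boot`.
#' @export
estimate_bias <- function(counts, karyotype, events_per_cell_mean = NULL,
                          method = c("generative", "single_event"),
                          n_boot = 1000, conf_level = 0.95, seed = NULL,
                          w_cap = 1e6, grid_size = 201) {
  stopifnot(inherits(karyotype, "karyotype"))
  method <- match.arg(method)
  n_cells <- NA_real_
  if (inherits(counts, "count_table")) {
    n_cells <- counts$n_cells
    n_TFs <- counts$n_TFs
    counts <- counts$counts
  } else {
    n_TFs <- sum(counts) / 2
  }
  categories <- .karyotype_categories(karyotype)
  O <- stats::setNames(numeric(length(categories)), categories)
  unknown <- setdiff(names(counts), categories)
  if (length(unknown) > 0) {
    stop("counts contain categories absent from the karyotype: ",
      paste(unknown, collapse = ", "), call. = FALSE)
  }
  O[names(counts)] <- counts
  N <- sum(O)
  if (N <= 0) {
    stop("counts must have a positive total", call. = FALSE)
  }
  if (method == "generative" && is.null(events_per_cell_mean)) {
    if (is.finite(n_cells) && n_cells > 0) {
      events_per_cell_mean <- n_TFs / n_cells
    } else {
      method <- "single_event"
    }
  }

  grid <- .bias_grid(karyotype, method, events_per_cell_mean, w_cap,
    grid_size)
  ll <- as.vector(grid$logQ %*% O)
  est <- .grid_argmax(grid$logw, matrix(ll, ncol = 1))
  w_hat <- exp(est$logw_hat)
  capped <- est$at_upper_edge || est$at_lower_edge

  ci_low <- NA_real_
  ci_high <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    B <- stats::rmultinom(n_boot, N, O / N)
    LLb <- grid$logQ %*% B
    bs <- .grid_argmax(grid$logw, LLb)
    wb <- exp(bs$logw_hat)
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(wb, c(alpha, 1 - alpha), names = FALSE, type = 7)
    ci_low <- qs[1]
    ci_high <- qs[2]
  }
  structure(
    list(
      w_hat = w_hat, log_likelihood = max(ll),
      ci_low = ci_low, ci_high = ci_high,
      converged = TRUE, capped = capped,
      method = method, events_per_cell_mean = events_per_cell_mean,
      n_boot = n_boot, conf_level = conf_level, n_FT = N
    ),
    class = "bias_estimate"
  )
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf(
    "Heterochromatin fusigenicity weight: w_hat = %.4g (%g%% CI %.4g-%.4g)%s\n",
    x$w_hat,
    100 * x$conf_level, x$ci_low, x$ci_high,
    if (x$capped) "  [at bound]" else ""
  ))
  cat(sprintf("  method = %s, n_FT = %d, bootstrap = %d\n",
    x$method, as.integer(x$n_FT), x$n_boot))
  invisible(x)
}
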