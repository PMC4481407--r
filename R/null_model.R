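# Random-involvement null model: a fusion event joins an unordered pair of
# distinct telomeres chosen uniformly, so a category's share of fused
# telomeres equals its share of telomere slots.

#' Expected fused-telomere frequencies under random involvement
#'
#' Under the random-pairing null every telomere slot is equally likely to be
#' consumed by a fusion, so the expected fraction of fused telomeres (FTs)
#' falling in a category is its slot count divided by the karyotype total.
#' For the wildtype male this gives A 50%, XL 6.25%, XR 6.25%, 4th 25%,
#' Y 12.5%; for the wildtype female A 50%, XL 12.5%, XR 12.5%, 4th 25%.
#'
#' @param karyotype a `karyotype` object with at least two telomeres.
#' @return Named numeric vector of fractions summing to 1.
#' @seealso [enumerate_pair_space()] for the brute-force enumeration that
#'   reproduces these values as pair-space marginals.
#' @export
expected_involvement_frequencies <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  if (karyotype$total < 2) {
    stop("karyotype must contain at least two telomeres", call. = FALSE)
  }
  cen <- telomere_census(karyotype)
  cen / karyotype$total
}

#' Expected fused-telomere counts for a given total
#'
#' Scales a vector of expected frequencies to a total FT count, the way
#' expected per-category counts are derived from each sample's own observed
#' FT total.
#'
#' @param total_FTs nonnegative total number of fused telomeres.
#' @param freq named frequencies summing to 1 (see
#'   [expected_involvement_frequencies()]).
#' @return Named numeric vector summing to `total_FTs`.
#' @export
expected_counts <- function(total_FTs, freq) {
  if (!is.numeric(total_FTs) || length(total_FTs) != 1 || is.na(total_FTs) ||
      total_FTs < 0) {
    stop("total_FTs must be a single nonnegative number", call. = FALSE)
  }
  if (abs(sum(freq) - 1) > 1e-9) {
    stop("freq must sum to 1", call. = FALSE)
  }
  total_FTs * freq
}

#' Null probability that a fusing Y telomere forms a ring Y
#'
#' A ring Y arises when the YL and YS termini of the same Y chromosome fuse.
#' Under random pairing, the partner of a fusing Y telomere is uniform over
#' the remaining telomeres, so in a 16-telomere male complement the ring
#' probability is 1/15 given any Y-involving fusion, and 1/6 given that the
#' partner lies in the heterochromatic group (the other Y arm, XR, or a 4th
#' telomere).
#'
#' The default conditions per fusing Y telomere, which is what the printed
#' 1/15 corresponds to. `method = "pair_space"` instead conditions on the set
#' of Y-involving unordered pairs (the YL-YS pair is a single pair among the
#' 29 Y-involving pairs, giving 1/29); it is exposed as a documented
#' alternative, not used by default.
#'
#' @param karyotype a `karyotype` containing a Y chromosome (any chromosome
#'   named `"Y"`).
#' @param conditioning `"given_Y_fusion"` (partner unrestricted) or
#'   `"given_Y_het_partner"` (partner restricted to the heterochromatic
#'   categories XR, 4th, Y).
#' @param method `"per_telomere"` (default) or `"pair_space"`.
#' @return A single probability.
#' @export
ring_probability <- function(karyotype,
                             conditioning = c("given_Y_fusion",
                                              "given_Y_het_partner"),
                             method = c("per_telomere", "pair_space")) {
  stopifnot(inherits(karyotype, "karyotype"))
  conditioning <- match.arg(conditioning)
  method <- match.arg(method)
  tel <- karyotype$telomeres
  y_idx <- which(tel$chromosome == "Y")
  if (length(y_idx) == 0) {
    stop("karyotype contains no Y chromosome", call. = FALSE)
  }

  if (method == "per_telomere") {
    probs <- vapply(y_idx, function(i) {
      partners <- setdiff(seq_len(nrow(tel)), i)
      if (conditioning == "given_Y_het_partner") {
        partners <- partners[tel$category[partners] %in% HET_CATEGORIES]
      }
      if (length(partners) == 0) {
        stop("no eligible partner telomeres under this conditioning",
          call. = FALSE)
      }
      ring <- tel$copy[partners] == tel$copy[i]
      sum(ring) / length(partners)
    }, numeric(1))
    return(mean(probs))
  }

  ps <- enumerate_pair_space(karyotype)
  involved <- ps$n_y_endpoints > 0
  if (conditioning == "given_Y_het_partner") {
    involved <- involved &
      (ps$category1 %in% HET_CATEGORIES) & (ps$category2 %in% HET_CATEGORIES)
  }
  if (!any(involved)) {
    stop("no eligible pairs under this conditioning", call. = FALSE)
  }
  y_ring <- ps$is_ring & ps$n_y_endpoints == 2
  sum(y_ring & involved) / sum(involved)
}

#' Enumerate the unordered telomere pair space
#'
#' Brute-force oracle for the closed-form null: lists all C(n, 2) unordered
#' pairs of distinct telomeres with their categories, a ring flag (both ends
#' of the same chromosome copy) and the number of Y endpoints. Marginal
#' involvement fractions computed from this table equal
#' [expected_involvement_frequencies()] exactly.
#'
#' @param karyotype a `karyotype` object.
#' @return Data frame with one row per pair: `i`, `j` (telomere row indices),
#'   `end1`, `end2` (labels), `category1`, `category2`, `is_ring`,
#'   `n_y_endpoints`.
#' @export
enumerate_pair_space <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  tel <- karyotype$telomeres
  n <- nrow(tel)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  data.frame(
    i = i, j = j,
    end1 = tel$label[i], end2 = tel$label[j],
    category1 = tel$category[i], category2 = tel$category[j],
    is_ring = tel$copy[i] == tel$copy[j],
    n_y_endpoints = (tel$chromosome[i] == "Y") + (tel$chromosome[j] == "Y"),
    stringsAsFactors = FALSE
  )
}

#' Per-category involvement marginals of a pair space
#'
#' Fraction of pair endpoints falling in each category, over all enumerated
#' pairs. Used as the enumeration oracle against the closed-form null.
#'
#' @param pair_space output of [enumerate_pair_space()].
#' @param categories category names defining the output order.
#' @return Named numeric vector of fractions summing to 1.
#' @export
pair_space_marginals <- function(pair_space,
                                 categories = unique(c(pair_space$category1,
                                                       pair_space$category2))) {
  ends <- c(pair_space$category1, pair_space$category2)
  vapply(categories, function(cc) sum(ends == cc), numeric(1)) / length(ends)
}

#' Null-expectation table for a karyotype
#'
#' Per-category slot counts, expected frequencies/percentages and (optionally)
#' expected FT counts for a user-supplied total, in the fixed reporting order.
#'
#' @param karyotype a `karyotype` object.
#' @param total_FTs optional observed FT total; when given, an
#'   `expected_count` column is added.
#' @return Data frame with columns `category` (display labels; `Fourth`
#'   prints as `4th`), `member_count`, `expected_freq`, `expected_pct` and
#'   optionally `expected_count`.
#' @export
expectation_table <- function(karyotype, total_FTs = NULL) {
  cen <- telomere_census(karyotype)
  freq <- expected_involvement_frequencies(karyotype)
  disp <- ifelse(names(cen) %in% names(DISPLAY_LABELS),
    DISPLAY_LABELS[names(cen)], names(cen))
  out <- data.frame(
    category = unname(disp),
    member_count = as.integer(cen),
    expected_freq = unname(freq),
    expected_pct = unname(freq) * 100,
    stringsAsFactors = FALSE
  )
  if (!is.null(total_FTs)) {
    out$expected_count <- unname(expected_counts(total_FTs, freq))
  }
  out
}
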