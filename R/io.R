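# Tab-separated count-table files: a key-value metadata stanza in `#` lines,
# then a two-column body. Human-inspectable; write/read round-trips exactly.
#
#   # telofuse count_table v1
#   # n_cells	250
#   # n_TFs	240
#   # sta	22
#   # dta	218
#   # y_fusions	58
#   # y_rings	6
#   category	ft_count
#   A	212
#   ...

.META_KEYS <- c("n_cells", "n_TFs", "sta", "dta", "y_fusions", "y_rings")

.normalize_category <- function(x, line) {
  key <- tolower(trimws(x))
  map <- c(
    a = "A", xl = "XL", xr = "XR", y = "Y",
    fourth = "Fourth", "4th" = "Fourth", "4" = "Fourth"
  )
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop(sprintf("line %d: unknown category '%s'", line[bad][1], x[bad][1]),
      call. = FALSE)
  }
  out
}

#' Read a fused-telomere count table
#'
#' Parses the tab-separated count-table format written by
#' [write_count_table()]. Category names are matched case-insensitively and
#' `4th` is accepted as an alias of `Fourth`. Malformed headers, unknown
#' categories and negative or non-integer counts raise errors naming the
#' offending line.
#'
#' @param path path to a count-table file.
#' @return A [count_table()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- stats::setNames(as.list(rep(NA_real_, length(.META_KEYS))),
    .META_KEYS)
  for (ln in which(is_meta)) {
    m <- regmatches(lines[[ln]],
      regexec("^#\\s*([A-Za-z_]+)\t(.*)$", lines[[ln]]))[[1]]
    if (length(m) == 3 && m[2] %in% .META_KEYS) {
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.na(v) && trimws(m[3]) != "NA") {
        stop(sprintf("line %d: non-numeric value for %s", ln, m[2]),
          call. = FALSE)
      }
      meta[[m[2]]] <- v
    }
  }
  body <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body) == 0) {
    stop("no table body found in ", path, call. = FALSE)
  }
  hdr_line <- body[1]
  if (!identical(lines[[hdr_line]], "category\tft_count")) {
    stop(sprintf("line %d: malformed header (expected 'category\tft_count')",
      hdr_line), call. = FALSE)
  }
  rows <- body[-1]
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2)) {
    stop(sprintf("line %d: expected 2 tab-separated fields", rows[nf != 2][1]),
      call. = FALSE)
  }
  cats <- .normalize_category(vapply(parts, `[[`, "", 1), rows)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  if (any(is.na(vals))) {
    stop(sprintf("line %d: non-numeric count", rows[is.na(vals)][1]),
      call. = FALSE)
  }
  if (any(vals < 0)) {
    stop(sprintf("line %d: negative count", rows[vals < 0][1]), call. = FALSE)
  }
  if (any(vals != round(vals))) {
    stop(sprintf("line %d: non-integer count", rows[vals != round(vals)][1]),
      call. = FALSE)
  }
  if (anyDuplicated(cats)) {
    stop(sprintf("line %d: duplicated category", rows[duplicated(cats)][1]),
      call. = FALSE)
  }
  count_table(
    stats::setNames(vals, cats),
    n_cells = meta$n_cells,
    n_TFs = if (is.na(meta$n_TFs)) NULL else meta$n_TFs,
    sta = meta$sta, dta = meta$dta,
    y_fusions = meta$y_fusions, y_rings = meta$y_rings
  )
}

#' Write a fused-telomere count table
#'
#' @param x a [count_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  meta <- c(
    n_cells = x$n_cells, n_TFs = x$n_TFs, sta = x$sta, dta = x$dta,
    y_fusions = x$y_fusions, y_rings = x$y_rings
  )
  lines <- c(
    "# telofuse count_table v1",
    sprintf("# %s\t%s", names(meta), vapply(meta, format, "", digits = 15)),
    "category\tft_count",
    sprintf("%s\t%s", names(x$counts),
      vapply(unname(x$counts), format, "", digits = 15))
  )
  writeLines(lines, path)
  invisible(path)
}

# Echo resolved simulation parameters next to a written count table.
.write_sidecar <- function(params, path) {
  lines <- c(
    "# telofuse simulate config",
    sprintf("%s\t%s", names(params),
      vapply(params, function(v) format(v, digits = 15), ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Analyse one count table against the random-involvement null
#'
#' Runs the full inference stage on a single genotype: chi-square goodness of
#' fit of the per-category FT counts, the Eu/Het aggregation and its own
#' chi-square, the exact binomial ring-Y excess test (when the karyotype has a
#' Y and the table carries Y tallies) and the fusigenicity-weight estimate.
#'
#' @param counts a [count_table()].
#' @param karyotype the `karyotype` the counts refer to.
#' @param n_boot bootstrap resamples for [estimate_bias()].
#' @param seed optional seed for the bootstrap.
#' @return A `fusion_analysis` object (list with components `gof`, `eu_het`,
#'   `eu_het_gof`, `ring`, `bias`, `counts`).
#' @export
analyze_count_table <- function(counts, karyotype, n_boot = 1000,
                                seed = NULL) {
  stopifnot(inherits(counts, "count_table"), inherits(karyotype, "karyotype"))
  freq <- expected_involvement_frequencies(karyotype)
  obs <- stats::setNames(numeric(length(freq)), names(freq))
  obs[names(counts$counts)] <- counts$counts
  gof <- chisq_gof(obs, freq)
  eu <- aggregate_eu_het(obs)
  eu_freq <- aggregate_eu_het(freq)
  eu_gof <- chisq_gof(eu, eu_freq / sum(eu_freq))
  ring <- NULL
  if (any(karyotype$telomeres$chromosome == "Y") &&
      !is.na(counts$y_fusions) && !is.na(counts$y_rings)) {
    ring <- ring_excess_test(
      counts$y_fusions, counts$y_rings,
      ring_probability(karyotype, "given_Y_fusion")
    )
  }
  bias <- estimate_bias(counts, karyotype, n_boot = n_boot, seed = seed)
  structure(
    list(
      gof = gof, eu_het = eu, eu_het_gof = eu_gof, ring = ring, bias = bias,
      counts = counts, karyotype = karyotype
    ),
    class = "fusion_analysis"
  )
}

#' Write a tab-separated analysis report
#'
#' One row per genotype with observed and expected per-category FT counts,
#' the chi-square test (raw and Holm-adjusted p across genotypes), the Eu/Het
#' split, the ring-Y excess test and the fusigenicity-weight estimate.
#' Numbers are rendered with fixed precision so that a rerun on the same
#' inputs is byte-identical.
#'
#' @param results a `fusion_analysis` or a named list of them (names are the
#'   genotype labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "fusion_analysis")) {
    results <- list(genotype = results)
  }
  num <- function(x) {
    ifelse(is.na(x), "NA", sprintf("%.6g", x))
  }
  cats <- CATEGORY_LEVELS
  header <- c(
    "genotype", "n_cells", "n_FT",
    paste0("obs_", cats), paste0("exp_", cats),
    "chisq", "df", "p", "p_holm", "low_expected",
    "eu_FT", "het_FT", "eu_het_p",
    "y_fusions", "y_rings", "ring_obs_frac", "ring_exp_frac", "ring_p",
    "w_hat", "w_ci_low", "w_ci_high", "w_capped"
  )
  lines <- paste(header, collapse = "\t")
  if (length(results) > 0) {
    praw <- vapply(results, function(r) r$gof$p_value, numeric(1))
    pholm <- stats::p.adjust(praw, method = "holm")
    for (g in seq_along(results)) {
      r <- results[[g]]
      getcat <- function(v) {
        out <- stats::setNames(rep(NA_real_, length(cats)), cats)
        out[names(v)[names(v) %in% cats]] <- v[names(v) %in% cats]
        out
      }
      obs <- getcat(r$gof$observed)
      expd <- getcat(r$gof$expected)
      ring <- r$ring
      row <- c(
        names(results)[g],
        num(r$counts$n_cells), num(sum(r$gof$observed)),
        num(obs), num(expd),
        num(r$gof$statistic), r$gof$df, num(r$gof$p_value), num(pholm[g]),
        if (r$gof$low_expected_warning) "yes" else "no",
        num(r$eu_het[["Eu"]]), num(r$eu_het[["Het"]]),
        num(r$eu_het_gof$p_value),
        if (is.null(ring)) rep("NA", 5) else c(
          num(ring$y_fusion_count), num(ring$y_ring_count),
          num(ring$observed_fraction), num(ring$expected_fraction),
          num(ring$p_value)
        ),
        num(r$bias$w_hat), num(r$bias$ci_low), num(r$bias$ci_high),
        if (r$bias$capped) "yes" else "no"
      )
      lines <- c(lines, paste(row, collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
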