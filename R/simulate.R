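# Monte Carlo metaphase simulator. Fusion events are sampled sequentially
# without replacement from the unordered pair space, with pair probability
# proportional to the product of the two telomere weights; heterochromatin-
# class telomeres carry weight w, all others weight 1, so w = 1 recovers the
# random-involvement null exactly.

#' Fusigenicity bias model
#'
#' Parameters of the generative model for metaphase fusion patterns.
#'
#' @param het_weight relative fusigenicity `w > 0` of heterochromatin-class
#'   telomeres (YL, YS, XR, 4L in the wildtype complement); 1 is the random
#'   null.
#' @param p_G1 probability that a fusion arose in G1 and is therefore scored
#'   as a double telomere association (DTA); the complement is scored STA.
#'   Default 0.9: a package default reflecting the strong DTA excess seen in
#'   all fly telomere-fusion mutants, not a measured value.
#' @param events_per_cell_mean Poisson mean of fusion events per cell,
#'   truncated at `floor(free telomere slots / 2)`. Default 1, the weak-mutant
#'   regime of roughly one fusion per cell.
#' @param allow_sister also allow a telomere to fuse with its own sister
#'   chromatid; such events consume one slot, count 2 FTs in that telomere's
#'   category and never join chromosomes.
#' @param ha_dta_censoring emulate the scoring convention that fusions between
#'   two heterochromatic-group telomeres are always recorded as DTAs (sister
#'   chromatids cannot be resolved in heterochromatin).
#' @return A `bias_model` object (list).
#' @export
bias_model <- function(het_weight = 1, p_G1 = 0.9, events_per_cell_mean = 1,
                       allow_sister = FALSE, ha_dta_censoring = FALSE) {
  if (!is.numeric(het_weight) || length(het_weight) != 1 || het_weight <= 0) {
    stop("het_weight must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p_G1) || p_G1 < 0 || p_G1 > 1) {
    stop("p_G1 must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(events_per_cell_mean) || events_per_cell_mean <= 0) {
    stop("events_per_cell_mean must be positive", call. = FALSE)
  }
  structure(
    list(
      het_weight = het_weight, p_G1 = p_G1,
      events_per_cell_mean = events_per_cell_mean,
      allow_sister = isTRUE(allow_sister),
      ha_dta_censoring = isTRUE(ha_dta_censoring)
    ),
    class = "bias_model"
  )
}

# Precomputed event space for one karyotype/bias: all unordered pairs of
# distinct telomeres (plus optional sister self-events), with sampling
# weights and the per-event tallies needed for counting.
.pair_table <- function(karyotype, bias) {
  tel <- karyotype$telomeres
  n <- nrow(tel)
  wtel <- ifelse(tel$chromatin_class == "heterochromatin", bias$het_weight, 1)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]
  j <- idx[, 2]
  if (bias$allow_sister) {
    i <- c(i, seq_len(n))
    j <- c(j, seq_len(n))
  }
  cats <- .karyotype_categories(karyotype)
  cat_code <- match(tel$category, cats)
  het_group <- tel$category %in% HET_CATEGORIES
  list(
    n_tel = n,
    i = i, j = j,
    w = wtel[i] * wtel[j],
    cat1 = cat_code[i], cat2 = cat_code[j],
    categories = cats,
    labels1 = tel$label[i], labels2 = tel$label[j],
    ring = tel$copy[i] == tel$copy[j] & i != j,
    n_y = (tel$chromosome[i] == "Y") + (tel$chromosome[j] == "Y"),
    het_het = het_group[i] & het_group[j],
    sister = i == j
  )
}

# Sequential weighted sampling without replacement of event rows.
.sample_event_rows <- function(pt, n_events) {
  if (n_events == 0) {
    return(integer(0))
  }
  if (n_events == 1) {
    return(sample.int(length(pt$w), 1L, prob = pt$w))
  }
  free <- rep(TRUE, pt$n_tel)
  rows <- integer(n_events)
  for (e in seq_len(n_events)) {
    ok <- which(free[pt$i] & free[pt$j])
    if (length(ok) == 0) {
      stop("no free telomere pair left for event ", e, call. = FALSE)
    }
    r <- ok[sample.int(length(ok), 1L, prob = pt$w[ok])]
    rows[e] <- r
    free[pt$i[r]] <- FALSE
    free[pt$j[r]] <- FALSE
  }
  rows
}

.event_associations <- function(pt, rows, bias) {
  assoc <- ifelse(stats::runif(length(rows)) < bias$p_G1, "DTA", "STA")
  if (bias$ha_dta_censoring) {
    assoc[pt$het_het[rows]] <- "DTA"
  }
  assoc[pt$sister[rows]] <- "STA" # a sister self-fusion is an STA by definition
  assoc
}

#' Simulate one metaphase spread
#'
#' Draws `n_events` fusion events sequentially without replacement (pair
#' probability proportional to the product of the telomere weights), labels
#' each STA or DTA, and derives the resulting chain/ring structures.
#'
#' @param karyotype a `karyotype` object.
#' @param bias a [bias_model()].
#' @param n_events number of fusion events, between 0 and half the telomere
#'   count.
#' @param seed optional integer seed for reproducibility.
#' @return A `metaphase` object: list with `karyotype`, `events` (data frame
#'   `end1`, `end2`, `association`) and `structures` (see
#'   [derive_structures()]).
#' @export
simulate_metaphase <- function(karyotype, bias = bias_model(), n_events,
                               seed = NULL) {
  stopifnot(inherits(karyotype, "karyotype"), inherits(bias, "bias_model"))
  max_events <- floor(karyotype$total / 2)
  if (!is.numeric(n_events) || n_events < 0 || n_events > max_events) {
    stop(sprintf("n_events must lie in [0, %d]", max_events), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pt <- .pair_table(karyotype, bias)
  rows <- .sample_event_rows(pt, n_events)
  events <- data.frame(
    end1 = pt$labels1[rows],
    end2 = pt$labels2[rows],
    association = .event_associations(pt, rows, bias),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      karyotype = karyotype,
      events = events,
      structures = derive_structures(events, karyotype)
    ),
    class = "metaphase"
  )
}

#' Derive chains and rings from fusion events
#'
#' Models each chromosome copy as a node with two ports (its two telomeres)
#' and each fusion event as an edge: connected paths become multicentric
#' chains (a lone unfused chromosome is a chain of length 1) and cycles become
#' rings (a chromosome whose two ends fused together is a ring of length 1).
#' Sister self-fusions consume a telomere but never join chromosomes.
#'
#' Output is canonicalized: each chain is listed from the end giving the
#' lexicographically smaller copy sequence, each ring starts at its smallest
#' copy and runs in the lexicographically smaller direction, and structures
#' are sorted by their canonical sequence.
#'
#' @param events data frame with columns `end1`, `end2` (telomere labels as in
#'   `karyotype$telomeres$label`); each telomere may appear in at most one
#'   event.
#' @param karyotype the `karyotype` the labels refer to.
#' @return List of structures; each is a list with `type` (`"chain"` or
#'   `"ring"`), `copies` (chromosome copy ids), `chromosomes`,
#'   `n_chromosomes` and `n_events`.
#' @examples
#' kar <- build_karyotype("male")
#' ev <- data.frame(end1 = c("4R.1", "YL.1"), end2 = c("YS.1", "XR.1"))
#' str <- derive_structures(ev, kar)
#' str[[1]]$chromosomes # tricentric 4-Y-X chain
#' @export
derive_structures <- function(events, karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  tel <- karyotype$telomeres
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) > 0) {
    bad <- !(c(events$end1, events$end2) %in% tel$label)
    if (any(bad)) {
      stop("unknown telomere label(s): ",
        paste(unique(c(events$end1, events$end2)[bad]), collapse = ", "),
        call. = FALSE)
    }
    sister <- events$end1 == events$end2
    used <- c(events$end1, events$end2[!sister])
    if (anyDuplicated(used)) {
      stop("telomere used by more than one fusion event: ",
        paste(unique(used[duplicated(used)]), collapse = ", "),
        call. = FALSE)
    }
  }

  partner <- stats::setNames(rep(NA_character_, nrow(tel)), tel$label)
  if (nrow(events) > 0) {
    link <- events[events$end1 != events$end2, , drop = FALSE]
    partner[link$end1] <- link$end2
    partner[link$end2] <- link$end1
  }
  # other telomere of the same chromosome copy
  other <- vapply(seq_len(nrow(tel)), function(k) {
    tel$label[tel$copy == tel$copy[k] & tel$label != tel$label[k]]
  }, character(1))
  other <- stats::setNames(other, tel$label)
  copy_of <- stats::setNames(tel$copy, tel$label)

  copies <- sort(unique(tel$copy))
  visited <- stats::setNames(rep(FALSE, length(copies)), copies)
  structures <- list()

  walk <- function(start_label) {
    # enter the chain/ring at start_label, exit each copy by its other end
    seq_copies <- character(0)
    cur <- start_label
    repeat {
      seq_copies <- c(seq_copies, copy_of[[cur]])
      nxt <- partner[[other[[cur]]]]
      if (is.na(nxt) || copy_of[[nxt]] == seq_copies[[1]]) {
        return(list(copies = seq_copies, closed = !is.na(nxt)))
      }
      cur <- nxt
    }
  }

  # chains: start from copies with at least one unfused end
  free_end <- tapply(is.na(partner), copy_of[tel$label], sum)
  for (cp in copies) {
    if (visited[[cp]] || free_end[[cp]] == 0) next
    ends <- tel$label[tel$copy == cp]
    start <- ends[is.na(partner[ends])][[1]]
    w <- walk(start)
    visited[w$copies] <- TRUE
    fwd <- w$copies
    rev_ <- rev(fwd)
    chosen <- if (paste(fwd, collapse = "|") <= paste(rev_, collapse = "|")) {
      fwd
    } else {
      rev_
    }
    structures[[length(structures) + 1L]] <- list(
      type = "chain", copies = chosen,
      chromosomes = sub("\\.[0-9]+$", "", chosen),
      n_chromosomes = length(chosen), n_events = length(chosen) - 1L
    )
  }
  # remaining copies belong to rings
  for (cp in copies) {
    if (visited[[cp]]) next
    start <- tel$label[tel$copy == cp][[1]]
    w <- walk(start)
    visited[w$copies] <- TRUE
    ring <- w$copies
    k <- length(ring)
    cands <- list()
    for (dir_seq in list(ring, rev(ring))) {
      s <- which(dir_seq == min(dir_seq))[[1]]
      cands[[length(cands) + 1L]] <-
        dir_seq[((seq_len(k) + s - 2L) %% k) + 1L]
    }
    keys <- vapply(cands, paste, character(1), collapse = "|")
    chosen <- cands[[order(keys)[1]]]
    structures[[length(structures) + 1L]] <- list(
      type = "ring", copies = chosen,
      chromosomes = sub("\\.[0-9]+$", "", chosen),
      n_chromosomes = k, n_events = k
    )
  }
  keys <- vapply(structures, function(s) {
    paste(s$type, paste(s$copies, collapse = "|"))
  }, character(1))
  structures[order(keys)]
}

#' Fused-telomere count table
#'
#' Container for the S1-Table-shaped observable: per-category fused-telomere
#' (FT) counts plus cell, fusion, STA/DTA and Y tallies. Each fusion event
#' contributes two FTs, so the category counts sum to twice the number of
#' fusions. `y_fusions` counts fused Y telomeres and `y_rings` the fused Y
#' telomeres whose partner is the other arm of the same Y (2 per ring-Y
#' event); this per-telomere convention matches the 1/15 null of
#' [ring_probability()].
#'
#' @param counts named nonnegative numeric vector of FT counts by category.
#' @param n_cells number of metaphases scored.
#' @param n_TFs number of fusion events; defaults to `sum(counts) / 2`.
#' @param sta,dta STA/DTA event tallies.
#' @param y_fusions,y_rings fused-Y-telomere tallies (see above).
#' @return A `count_table` object.
#' @export
count_table <- function(counts, n_cells = NA_integer_, n_TFs = NULL,
                        sta = NA_integer_, dta = NA_integer_,
                        y_fusions = NA_integer_, y_rings = NA_integer_) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be a named vector", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (is.null(n_TFs)) {
    n_TFs <- sum(counts) / 2
  }
  if (abs(sum(counts) - 2 * n_TFs) > 1e-9) {
    stop("category FT counts must sum to 2 * n_TFs", call. = FALSE)
  }
  if (!is.na(y_fusions) && !is.na(y_rings) && y_rings > y_fusions) {
    stop("y_rings cannot exceed y_fusions", call. = FALSE)
  }
  structure(
    list(
      counts = counts, n_cells = n_cells, n_TFs = n_TFs,
      sta = sta, dta = dta, y_fusions = y_fusions, y_rings = y_rings
    ),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "<count_table> %s cells, %s fusions (STA %s / DTA %s), Y FTs %s (ring %s)\n",
    x$n_cells, x$n_TFs, x$sta, x$dta, x$y_fusions, x$y_rings
  ))
  print(data.frame(category = names(x$counts), ft_count = unname(x$counts),
    row.names = NULL))
  invisible(x)
}

#' Count fused telomeres over metaphases
#'
#' Aggregates a list of simulated (or hand-built) metaphases into a
#' [count_table()]: each fusion event contributes one FT to the category of
#' each of its two telomeres (a sister self-fusion contributes both to its own
#' category).
#'
#' @param metaphases a `metaphase` object or a non-empty list of them, all on
#'   the same karyotype.
#' @return A `count_table`.
#' @export
count_fused_telomeres <- function(metaphases) {
  if (inherits(metaphases, "metaphase")) {
    metaphases <- list(metaphases)
  }
  if (length(metaphases) == 0) {
    stop("need at least one metaphase", call. = FALSE)
  }
  kar <- metaphases[[1]]$karyotype
  tel <- kar$telomeres
  catmap <- stats::setNames(tel$category, tel$label)
  copymap <- stats::setNames(tel$copy, tel$label)
  chrmap <- stats::setNames(tel$chromosome, tel$label)
  cats <- .karyotype_categories(kar)
  counts <- stats::setNames(numeric(length(cats)), cats)
  n_TFs <- 0L
  sta <- 0L
  dta <- 0L
  yf <- 0L
  yr <- 0L
  for (m in metaphases) {
    ev <- m$events
    if (nrow(ev) == 0) next
    c1 <- catmap[ev$end1]
    c2 <- catmap[ev$end2]
    tt <- table(factor(c(c1, c2), levels = cats))
    counts <- counts + as.numeric(tt)
    n_TFs <- n_TFs + nrow(ev)
    if (!is.null(ev$association)) {
      sta <- sta + sum(ev$association == "STA")
      dta <- dta + sum(ev$association == "DTA")
    }
    y_ends <- (chrmap[ev$end1] == "Y") + (chrmap[ev$end2] == "Y")
    yf <- yf + sum(y_ends)
    ring_y <- ev$end1 != ev$end2 & copymap[ev$end1] == copymap[ev$end2] &
      y_ends == 2
    yr <- yr + 2L * sum(ring_y)
  }
  count_table(counts,
    n_cells = length(metaphases), n_TFs = n_TFs,
    sta = sta, dta = dta, y_fusions = yf, y_rings = yr
  )
}

#' Simulate a scored fusion experiment
#'
#' Simulates `n_cells` metaphases (per-cell event count Poisson with mean
#' `bias$events_per_cell_mean`, truncated at the number of free slot pairs)
#' and aggregates them into a [count_table()]. Fully reproducible for a given
#' seed: all random draws are consumed from the single seeded stream in a
#' fixed order.
#'
#' @param karyotype a `karyotype` object.
#' @param bias a [bias_model()].
#' @param n_cells number of cells to score (>= 1).
#' @param seed optional integer seed.
#' @return A `count_table` with an attribute `params` echoing the resolved
#'   simulation parameters.
#' @examples
#' kar <- build_karyotype("male")
#' ct <- simulate_experiment(kar, bias_model(het_weight = 5), 250, seed = 1)
#' ct
#' @export
simulate_experiment <- function(karyotype, bias = bias_model(), n_cells,
                                seed = NULL) {
  stopifnot(inherits(karyotype, "karyotype"), inherits(bias, "bias_model"))
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("n_cells must be at least 1", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (!is.null(seed)) set.seed(seed)
  pt <- .pair_table(karyotype, bias)
  max_events <- floor(karyotype$total / 2)

  nvec <- pmin(stats::rpois(n_cells, bias$events_per_cell_mean), max_events)
  single <- which(nvec == 1L)
  multi <- which(nvec >= 2L)

  rows <- integer(0)
  if (length(single) > 0) {
    rows <- sample.int(length(pt$w), length(single), replace = TRUE,
      prob = pt$w)
  }
  for (cell in multi) {
    rows <- c(rows, .sample_event_rows(pt, nvec[cell]))
  }

  cats <- pt$categories
  counts <- stats::setNames(numeric(length(cats)), cats)
  if (length(rows) > 0) {
    counts <- counts +
      tabulate(c(pt$cat1[rows], pt$cat2[rows]), nbins = length(cats))
  }
  assoc <- .event_associations(pt, rows, bias)
  y_ring_rows <- pt$ring[rows] & pt$n_y[rows] == 2
  out <- count_table(counts,
    n_cells = n_cells, n_TFs = length(rows),
    sta = sum(assoc == "STA"), dta = sum(assoc == "DTA"),
    y_fusions = sum(pt$n_y[rows]), y_rings = 2L * sum(y_ring_rows)
  )
  attr(out, "params") <- list(
    sex = karyotype$sex, variant = karyotype$variant,
    het_weight = bias$het_weight, p_G1 = bias$p_G1,
    events_per_cell_mean = bias$events_per_cell_mean,
    allow_sister = bias$allow_sister,
    ha_dta_censoring = bias$ha_dta_censoring,
    n_cells = n_cells, seed = if (is.null(seed)) NA else seed
  )
  out
}

#' @export
print.metaphase <- function(x, ...) {
  cat(sprintf(
    "<metaphase> %d fusion events, %d structures\n",
    nrow(x$events), length(x$structures)
  ))
  for (s in x$structures) {
    cat(sprintf("  %s: %s\n", s$type, paste(s$chromosomes, collapse = "-")))
  }
  invisible(x)
}
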