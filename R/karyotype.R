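# Reporting categories used throughout. "Fourth" aggregates 4L and 4R, which
# cannot be distinguished cytologically; "A" aggregates the major autosome
# arms 2L, 2R, 3L and 3R.
CATEGORY_LEVELS <- c("A", "XL", "XR", "Fourth", "Y")
EU_CATEGORIES <- c("A", "XL")
HET_CATEGORIES <- c("XR", "Fourth", "Y")
CHROMATIN_LEVELS <- c("heterochromatin", "TAS", "fourth_type")

# Display labels for user-facing tables ("Fourth" prints as "4th").
DISPLAY_LABELS <- c(A = "A", XL = "XL", XR = "XR", Fourth = "4th", Y = "Y")

# Default subtelomeric chromatin class of each arm: the Y arms, XR and 4L abut
# constitutive heterochromatin; XL and the major autosome arms carry TAS
# repeats; 4R has a chromatin type of its own.
.default_chromatin <- c(
  XL = "TAS", XR = "heterochromatin",
  YL = "heterochromatin", YS = "heterochromatin",
  `2L` = "TAS", `2R` = "TAS", `3L` = "TAS", `3R` = "TAS",
  `4L` = "heterochromatin", `4R` = "fourth_type"
)

.standard_category <- function(chromosome, arm) {
  ifelse(chromosome %in% c("2", "3"), "A",
    ifelse(chromosome == "4", "Fourth",
      ifelse(chromosome == "Y", "Y",
        ifelse(chromosome == "X" & arm == "L", "XL",
          ifelse(chromosome == "X" & arm == "R", "XR", NA_character_)
        )
      )
    )
  )
}

#' Build a Drosophila melanogaster karyotype
#'
#' Constructs the full telomere complement of a diploid cell at the
#' unreplicated-chromosome level (sister chromatids collapsed): 16 telomere
#' slots for both sexes. Each telomere carries a subtelomeric chromatin class;
#' the heterochromatin class (YL, YS, XR, 4L) is the one that can carry a
#' fusigenicity bias in [simulate_experiment()].
#'
#' The `marked_Y` variant models a Y chromosome whose YL end carries an
#' appended euchromatic fragment: the complement is identical to the wildtype
#' male one but YL is reclassified from heterochromatin to a TAS-like
#' euchromatic context.
#'
#' @param sex `"male"` or `"female"`.
#' @param variant `"wildtype"` or `"marked_Y"` (males only).
#' @param chromatin_overrides optional named character vector of per-arm
#'   chromatin-class overrides, e.g. `c(YL = "TAS")`; names are arm labels
#'   (`XL`, `XR`, `YL`, `YS`, `2L`, ..., `4R`), values one of
#'   `"heterochromatin"`, `"TAS"`, `"fourth_type"`.
#' @return A `karyotype` object: a list with elements `telomeres` (data frame
#'   with columns `chromosome`, `arm`, `homolog`, `chromatin_class`,
#'   `category`, `label`, `copy`), `sex`, `variant` and `total`.
#' @examples
#' kar <- build_karyotype("male")
#' telomere_census(kar)
#' @export
build_karyotype <- function(sex = c("male", "female"),
                            variant = c("wildtype", "marked_Y"),
                            chromatin_overrides = NULL) {
  sex <- match.arg(sex)
  variant <- match.arg(variant)
  if (variant == "marked_Y" && sex != "male") {
    stop("the marked_Y variant requires a male karyotype", call. = FALSE)
  }

  auto <- expand.grid(
    chromosome = c("2", "3", "4"), arm = c("L", "R"), homolog = 1:2,
    stringsAsFactors = FALSE
  )
  sexchr <- if (sex == "male") {
    data.frame(
      chromosome = c("X", "X", "Y", "Y"),
      arm = c("L", "R", "L", "S"),
      homolog = 1L
    )
  } else {
    data.frame(
      chromosome = rep(c("X", "X"), 2),
      arm = rep(c("L", "R"), 2),
      homolog = rep(1:2, each = 2)
    )
  }
  tel <- rbind(sexchr, auto)
  armkey <- paste0(tel$chromosome, tel$arm)
  tel$chromatin_class <- unname(.default_chromatin[armkey])
  if (variant == "marked_Y") {
    tel$chromatin_class[armkey == "YL"] <- "TAS"
  }
  if (!is.null(chromatin_overrides)) {
    if (is.null(names(chromatin_overrides)) ||
        !all(names(chromatin_overrides) %in% armkey)) {
      stop("chromatin_overrides must be named by arm labels present in the karyotype",
        call. = FALSE)
    }
    if (!all(chromatin_overrides %in% CHROMATIN_LEVELS)) {
      stop("chromatin_overrides values must be one of: ",
        paste(CHROMATIN_LEVELS, collapse = ", "), call. = FALSE)
    }
    for (a in names(chromatin_overrides)) {
      tel$chromatin_class[armkey == a] <- chromatin_overrides[[a]]
    }
  }
  as_karyotype(tel, sex = sex, variant = variant)
}

#' Assemble a karyotype from a telomere table
#'
#' Low-level constructor used by [build_karyotype()] and available for toy or
#' rearranged complements (tests, custom configurations). Every chromosome
#' copy (chromosome x homolog) must contribute exactly two telomeres.
#'
#' @param telomeres data frame with columns `chromosome`, `arm`, `homolog`,
#'   `chromatin_class` and optionally `category` (derived from the standard
#'   chromosome naming when absent; unknown chromosomes fall back to their own
#'   name as category).
#' @param sex,variant metadata labels stored on the object.
#' @return A `karyotype` object.
#' @export
as_karyotype <- function(telomeres, sex = "custom", variant = "custom") {
  req <- c("chromosome", "arm", "homolog", "chromatin_class")
  if (!all(req %in% names(telomeres))) {
    stop("telomere table must have columns: ", paste(req, collapse = ", "),
      call. = FALSE)
  }
  tel <- as.data.frame(telomeres, stringsAsFactors = FALSE)
  tel$chromosome <- as.character(tel$chromosome)
  tel$arm <- as.character(tel$arm)
  tel$homolog <- as.integer(tel$homolog)
  if (!all(tel$chromatin_class %in% CHROMATIN_LEVELS)) {
    stop("unknown chromatin_class; must be one of: ",
      paste(CHROMATIN_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (is.null(tel$category)) {
    cat0 <- .standard_category(tel$chromosome, tel$arm)
    tel$category <- ifelse(is.na(cat0), tel$chromosome, cat0)
  }
  tel$label <- sprintf("%s%s.%d", tel$chromosome, tel$arm, tel$homolog)
  tel$copy <- sprintf("%s.%d", tel$chromosome, tel$homolog)
  if (anyDuplicated(tel$label)) {
    stop("duplicated telomere (chromosome, arm, homolog)", call. = FALSE)
  }
  ends_per_copy <- table(tel$copy)
  if (any(ends_per_copy != 2L)) {
    stop("every chromosome copy must have exactly two telomeres; offending: ",
      paste(names(ends_per_copy)[ends_per_copy != 2L], collapse = ", "),
      call. = FALSE)
  }
  rownames(tel) <- NULL
  structure(
    list(telomeres = tel, sex = sex, variant = variant, total = nrow(tel)),
    class = "karyotype"
  )
}

# Category names present in a karyotype, standard reporting order first.
.karyotype_categories <- function(karyotype) {
  cats <- unique(karyotype$telomeres$category)
  c(CATEGORY_LEVELS[CATEGORY_LEVELS %in% cats],
    sort(setdiff(cats, CATEGORY_LEVELS)))
}

#' Telomere census by reporting category
#'
#' Counts the telomere slots of a karyotype per reporting category. The
#' counts, divided by the total number of telomeres, are exactly the expected
#' involvement frequencies under the random-pairing null.
#'
#' @param karyotype a `karyotype` object.
#' @return Named integer vector of slot counts; sums to the karyotype total.
#' @export
telomere_census <- function(karyotype) {
  stopifnot(inherits(karyotype, "karyotype"))
  cats <- .karyotype_categories(karyotype)
  out <- vapply(cats, function(cc) {
    sum(karyotype$telomeres$category == cc)
  }, integer(1))
  out
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf(
    "<karyotype> %s / %s: %d telomeres, %d chromosome copies\n",
    x$sex, x$variant, x$total, x$total / 2
  ))
  cen <- telomere_census(x)
  het <- vapply(names(cen), function(cc) {
    sum(x$telomeres$category == cc &
          x$telomeres$chromatin_class == "heterochromatin")
  }, integer(1))
  print(data.frame(
    category = names(cen), slots = as.integer(cen),
    heterochromatin_class = as.integer(het), row.names = NULL
  ))
  invisible(x)
}

#' Read a karyotype configuration file
#'
#' Parses a small key-value text format:
#' \preformatted{
#' sex	male
#' variant	wildtype
#' override	YL	TAS
#' }
#' Lines starting with `#` and blank lines are ignored; `override` lines may
#' be repeated.
#'
#' @param path path to the configuration file.
#' @return A `karyotype` object built by [build_karyotype()].
#' @export
read_karyotype_config <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  sex <- "male"
  variant <- "wildtype"
  overrides <- character(0)
  for (ln in keep) {
    parts <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    key <- trimws(parts[[1]])
    if (key == "sex" && length(parts) >= 2) {
      sex <- trimws(parts[[2]])
    } else if (key == "variant" && length(parts) >= 2) {
      variant <- trimws(parts[[2]])
    } else if (key == "override" && length(parts) >= 3) {
      overrides[trimws(parts[[2]])] <- trimws(parts[[3]])
    } else {
      stop(sprintf("karyotype config line %d: cannot parse '%s'", ln, lines[[ln]]),
        call. = FALSE)
    }
  }
  build_karyotype(sex, variant,
    chromatin_overrides = if (length(overrides)) overrides else NULL)
}
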