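#' Generate the packaged example datasets
#'
#' Writes deterministic synthetic fixtures to `dir`:
#' \describe{
#'   \item{`null_male.tsv`}{wildtype male, `w = 1` (random null), 250 cells.}
#'   \item{`peo_like_male.tsv`}{wildtype male, `w = 5`: a heterochromatin-
#'     biased pattern with a ring-Y excess, emulating the peo-type fusion
#'     pattern.}
#'   \item{`marked_y_biased.tsv`}{marked-Y male, `w = 5`: the same bias with
#'     the YL terminus made euchromatic.}
#' }
#' Each table gets a `.config` sidecar. The returned list also carries the
#' worked chain/ring topology examples (a ring autosome; a 4-Y-X tricentric;
#' an XR-4 fusion alongside an A-A-A-A chain) built with
#' [derive_structures()].
#'
#' @param dir output directory (created if needed).
#' @param seed integer root seed.
#' @param n_cells cells per simulated genotype.
#' @return Invisibly, a list with `paths` (named character vector) and
#'   `topologies` (named list of structure lists).
#' @export
make_fixtures <- function(dir, seed = 1L, n_cells = 250) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  male <- build_karyotype("male")
  female <- build_karyotype("female")
  marked <- build_karyotype("male", "marked_Y")

  specs <- list(
    null_male = list(kar = male, w = 1),
    peo_like_male = list(kar = male, w = 5),
    marked_y_biased = list(kar = marked, w = 5)
  )
  paths <- character(0)
  for (nm in names(specs)) {
    s <- specs[[nm]]
    ct <- simulate_experiment(s$kar, bias_model(het_weight = s$w),
      n_cells = n_cells, seed = seed)
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_count_table(ct, p)
    .write_sidecar(attr(ct, "params"), paste0(p, ".config"))
    paths[nm] <- p
  }

  topologies <- list(
    # ring autosome: the two ends of one chromosome 2 copy fuse
    fig_ring_autosome = derive_structures(
      data.frame(end1 = "2L.1", end2 = "2R.1"), female
    ),
    # tricentric 4-Y-X chain: 4R to YS, YL to XR
    fig_tricentric_4_Y_X = derive_structures(
      data.frame(end1 = c("4R.1", "YL.1"), end2 = c("YS.1", "XR.1")), male
    ),
    # XR-4 fusion plus an A-A-A-A multicentric chain
    fig_XR4_plus_AAAA = derive_structures(
      data.frame(
        end1 = c("XR.1", "2R.1", "2R.2", "3R.1"),
        end2 = c("4L.1", "2L.2", "3L.1", "3L.2")
      ), female
    )
  )
  invisible(list(paths = paths, topologies = topologies))
}
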