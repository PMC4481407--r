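# Shared fixtures built in code.

male_kar <- build_karyotype("male")
female_kar <- build_karyotype("female")
marked_kar <- build_karyotype("male", "marked_Y")

# A random toy karyotype: n_chr chromosomes, each with two arms, random
# chromatin classes and (optionally) random homolog counts. Categories fall
# back to the chromosome name, so these complements exercise the generic
# category machinery, not just the standard five.
random_toy_karyotype <- function(n_chr = NULL) {
  if (is.null(n_chr)) n_chr <- sample(2:6, 1)
  rows <- do.call(rbind, lapply(seq_len(n_chr), function(k) {
    n_hom <- sample(1:2, 1)
    expand.grid(
      chromosome = paste0("c", k), arm = c("L", "R"), homolog = seq_len(n_hom),
      stringsAsFactors = FALSE
    )
  }))
  rows$chromatin_class <- sample(c("heterochromatin", "TAS", "fourth_type"),
    nrow(rows), replace = TRUE)
  as_karyotype(rows)
}

# Toy containing only a Y chromosome (two arms, one copy).
single_y_karyotype <- function() {
  as_karyotype(data.frame(
    chromosome = "Y", arm = c("L", "S"), homolog = 1L,
    chromatin_class = "heterochromatin"
  ))
}
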