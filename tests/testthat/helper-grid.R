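# Exhaustive grid of valid lesion-descriptor combinations: every
# boolean/enum combination satisfying the schema invariants, with
# enhancing-component diameters spanning the large-component threshold.
# 57 rows: 1 no-mass + 2 (peritoneal yes/no) x (5 fatty + 9 solid +
# 14 cystic) archetypes.

rec_row <- function(...) oradsped:::.rec(id = "G", ...)

grid_valid_records <- function() {
  rows <- list(rec_row(mass = FALSE, perit = FALSE, malignant = FALSE))
  add <- function(...) rows[[length(rows) + 1]] <<- rec_row(...)
  for (perit in c(FALSE, TRUE)) {
    for (enh in c(0, 79, 80, 81, 200))
      add(mass = TRUE, perit = perit, fat = TRUE, enh = enh, size = 250,
          malignant = FALSE)
    for (t2 in c(TRUE, FALSE)) for (dwi in c(TRUE, FALSE)) {
      grades <- if (t2 && dwi) c(NA_character_, "hypo_or_iso", "hyper")
                else c("hypo_or_iso", "hyper")
      for (g in grades)
        add(mass = TRUE, perit = perit, fat = FALSE, solid = TRUE, t2 = t2,
            dwi = dwi, grade = g, malignant = FALSE)
    }
    for (loc in c("unilocular", "multilocular"))
      for (fl in c("simple", "endometriotic", "hemorrhagic",
                   "proteinaceous")) {
        walls <- if (fl == "simple") NA else c(TRUE, FALSE)
        for (w in walls)
          add(mass = TRUE, perit = perit, fat = FALSE, solid = FALSE,
              loc = loc, fluid = fl, wall = w, malignant = FALSE)
      }
  }
  out <- do.call(rbind, rows)
  out$id <- sprintf("G%03d", seq_len(nrow(out)))
  out$age_years <- 13
  out
}

# convenience: lesion_features for a one-off descriptor set
lf <- function(...) lesion_features(...)
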