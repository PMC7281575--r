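# Ion-form (adduct) tables used for m/z annotation and for the synthetic
# pathway-data generator. Theoretical m/z of a form applied to a neutral
# monoisotopic mass M is (multiplier * M + massShift) / |charge|.

PROTON <- 1.007276466

.ionFormTable <- function() {
  rbind(
    data.frame(name = "M+H[1+]",      massShift = PROTON,              charge = 1L,  multiplier = 1L, mode = "positive", isPrimary = TRUE),
    data.frame(name = "M+Na[1+]",     massShift = 22.989218,           charge = 1L,  multiplier = 1L, mode = "positive", isPrimary = TRUE),
    data.frame(name = "M-H2O+H[1+]",  massShift = PROTON - 18.010565,  charge = 1L,  multiplier = 1L, mode = "positive", isPrimary = TRUE),
    data.frame(name = "M+NH4[1+]",    massShift = 18.033823,           charge = 1L,  multiplier = 1L, mode = "positive", isPrimary = FALSE),
    data.frame(name = "M+K[1+]",      massShift = 38.963158,           charge = 1L,  multiplier = 1L, mode = "positive", isPrimary = FALSE),
    data.frame(name = "M+2H[2+]",     massShift = 2 * PROTON,          charge = 2L,  multiplier = 1L, mode = "positive", isPrimary = FALSE),
    data.frame(name = "2M+H[1+]",     massShift = PROTON,              charge = 1L,  multiplier = 2L, mode = "positive", isPrimary = FALSE),
    data.frame(name = "M-H[1-]",      massShift = -PROTON,             charge = -1L, multiplier = 1L, mode = "negative", isPrimary = TRUE),
    data.frame(name = "M-2H[2-]",     massShift = -2 * PROTON,         charge = -2L, multiplier = 1L, mode = "negative", isPrimary = TRUE),
    data.frame(name = "M-H2O-H[1-]",  massShift = -PROTON - 18.010565, charge = -1L, multiplier = 1L, mode = "negative", isPrimary = TRUE),
    data.frame(name = "M+Cl[1-]",     massShift = 34.969402,           charge = -1L, multiplier = 1L, mode = "negative", isPrimary = FALSE),
    data.frame(name = "M+FA-H[1-]",   massShift = 44.998201,           charge = -1L, multiplier = 1L, mode = "negative", isPrimary = FALSE),
    data.frame(name = "2M-H[1-]",     massShift = -PROTON,             charge = -1L, multiplier = 2L, mode = "negative", isPrimary = FALSE)
  )
}

#' Ion-form table for one ionization mode
#'
#' @param mode `"positive"` or `"negative"`.
#' @return data.frame with columns `name`, `massShift` (Da), `charge`,
#'   `multiplier` (2 for dimer forms), `mode`, `isPrimary`. The primary
#'   forms are M+H, M+Na and M-H2O+H (positive) and M-H, M-2H and
#'   M-H2O-H (negative): an empirical compound must contain at least one
#'   of them to survive primary-ion enforcement.
#' @export
ionForms <- function(mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  tab <- .ionFormTable()
  tab[tab$mode == mode, , drop = FALSE]
}

#' Normalize an ion-form name to its canonical spelling
#'
#' Ion-form labels occur in the wild with embedded spaces, Unicode minus
#' signs and bare-sign charge brackets (`[+]`, `[-]`). All such variants
#' map onto one canonical form so that `"M+H [1+]"`, `"M+H[1+]"` and
#' `"M−H[−]"` compare equal.
#'
#' @param name character vector of ion-form labels.
#' @return character vector of canonical names.
#' @export
normalizeIonName <- function(name) {
  x <- gsub("[[:space:]]+", "", name)
  x <- gsub("−", "-", x)
  x <- gsub("\\[\\+\\]", "[1+]", x)
  x <- gsub("\\[-\\]", "[1-]", x)
  x
}

#' Theoretical m/z of an ion form
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param form one row of [ionForms()] (or a list with `multiplier`,
#'   `massShift`, `charge`).
#' @return m/z in Thomson.
#' @export
theoreticalMz <- function(mass, form) {
  (form$multiplier * mass + form$massShift) / abs(form$charge)
}
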