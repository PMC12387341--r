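# Packaged reference tables: the 27-species screening panel, the published
# DAB-intensity table over stress/recovery phases A-N, and the per-species
# index values printed in the source study's running text.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "woodscreen", mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p))
    stopf("packaged fixture '%s' is missing or unreadable", file)
  p
}

#' Load the packaged woody-species panel
#'
#' Returns the 27 woody plant species screened for sequential drought-heat
#' stress tolerance, keyed by their short abbreviation codes (e.g. \code{"Qg"}
#' for \emph{Quercus glauca}).  These codes key every other table in the
#' package.
#'
#' @return A data frame with columns \code{code}, \code{scientific_name},
#'   \code{family}, \code{common_name}, one row per species, in panel order.
#' @export
#' @examples
#' sp <- load_species_table()
#' nrow(sp)           # 27
#' sp[sp$code == "Aj", "scientific_name"]
load_species_table <- function() {
  tab <- utils::read.csv(fixture_path("species_table.csv"),
                         stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("code", "scientific_name", "family", "common_name")
  if (!identical(names(tab), need))
    stopf("species fixture is corrupted: expected columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(tab$code))
    stopf("species fixture is corrupted: duplicated codes")
  if (nrow(tab) != 27L)
    stopf("species fixture is corrupted: expected 27 records, found %d",
          nrow(tab))
  tab
}

#' Load the packaged DAB staining intensity table
#'
#' The published background-corrected HSV-saturation means (0-255 scale) of
#' DAB-stained leaves for six tree species over the 14 experimental phases
#' A-N (control, hydrogen-peroxide positive control, drought, four heat
#' durations, seven recovery durations), with standard deviations over n = 3
#' replicates and Duncan-test letter groups.
#'
#' @return A data frame with columns \code{species}, \code{phase},
#'   \code{mean}, \code{sd}, \code{letter}; 6 species x 14 phases = 84 rows.
#' @seealso [dab_cell()] for single-cell lookup, [phase_schedule()] for the
#'   phase definitions.
#' @export
load_dab_table <- function() {
  tab <- utils::read.csv(fixture_path("dab_intensity.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character",
                                        "numeric", "numeric", "character"))
  need <- c("species", "phase", "mean", "sd", "letter")
  if (!identical(names(tab), need))
    stopf("DAB fixture is corrupted: expected columns %s",
          paste(need, collapse = ", "))
  phases <- phase_schedule()$phase
  sp <- unique(tab$species)
  if (length(sp) != 6L || nrow(tab) != 84L ||
      !all(tab$phase %in% phases) ||
      any(!stats::complete.cases(tab[c("mean", "sd")])) ||
      any(tab$sd < 0))
    stopf("DAB fixture is corrupted")
  tab$letter[is.na(tab$letter)] <- ""
  tab
}

#' Look up one cell of the DAB intensity table
#'
#' @param species species code (see [load_species_table()]).
#' @param phase phase label, one of \code{"A"} to \code{"N"}.
#' @param table the table to index; defaults to the packaged fixture.
#' @return A list with elements \code{mean}, \code{sd} and \code{letter}.
#' @export
#' @examples
#' dab_cell("Csin", "E")$mean   # 116.6
dab_cell <- function(species, phase, table = load_dab_table()) {
  i <- which(table$species == species & table$phase == phase)
  if (length(i) != 1L)
    stopf("no cell for species '%s', phase '%s'", species, phase)
  list(mean = table$mean[i], sd = table$sd[i], letter = table$letter[i])
}

#' Load the per-species index values printed in the source study
#'
#' Relative water content (percent) and electrolyte leakage index for the
#' species whose values appear as numbers in the study's running text.  The
#' \code{context} column distinguishes the pre-screening measurements
#' (\code{"prescreen"}: both RWC and ELI) from the later drought-only and
#' sequential drought+heat ELI evaluations (\code{"drought"},
#' \code{"dual_stress"}: ELI only, RWC is \code{NA}).  The full 27-species
#' screening values were published only graphically and are not packaged.
#'
#' @return A data frame with columns \code{code}, \code{context}, \code{rwc},
#'   \code{eli}.
#' @export
load_printed_indices <- function() {
  tab <- utils::read.csv(fixture_path("printed_indices.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "character",
                                        "numeric", "numeric"))
  need <- c("code", "context", "rwc", "eli")
  if (!identical(names(tab), need))
    stopf("printed-index fixture is corrupted")
  bad_rwc <- !is.na(tab$rwc) & (tab$rwc < 0 | tab$rwc > 100)
  if (any(bad_rwc) || any(tab$eli < 0, na.rm = TRUE))
    stopf("printed-index fixture is corrupted: value out of range")
  tab
}
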