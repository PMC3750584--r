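# Readers/writers for the delimited-text drug-screen panel formats and the
# versioned JSON artifact formats, plus the screen_dataset container.

#' Detect the field separator of a delimited text file
#'
#' Header sniffing: the candidate separator ("\t", "," or ";") splitting the
#' first line into the most fields wins.  Files exported from spreadsheets
#' come in unspecified dialects, so auto-detection is the default and an
#' explicit `sep` always overrides it.
#'
#' @param path file path.
#' @return single separator character.
#' @keywords internal
#' @noRd
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  cands <- c("\t", ",", ";")
  counts <- vapply(cands, function(s) {
    length(strsplit(header, s, fixed = TRUE)[[1]])
  }, integer(1))
  cands[which.max(counts)]
}

#' Read a drug x target EC50 panel
#'
#' The panel is a delimited text file with a header row of kinase target
#' names and one row per drug; the first column holds drug identifiers.
#' Cells are EC50 values in nM; an empty cell means the drug does not
#' interact with the target.
#'
#' @param path path to the delimited file (TSV/CSV auto-detected).
#' @param sep optional explicit field separator overriding auto-detection.
#' @return a list with elements `universe` (character vector of target names
#'   in file column order) and `profiles` (named list of per-drug EC50
#'   vectors; each a named numeric vector over the targets the drug hits).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("drug,KIT,ABL1", "imatinib,100,35", "toy,,12"), f)
#' p <- read_ec50_panel(f)
#' p$universe
#' p$profiles$imatinib
#' @export
read_ec50_panel <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("EC50 panel needs a drug column and >= 1 target column")
  universe <- colnames(tab)[-1]
  if (anyDuplicated(universe))
    stop("duplicate target name(s) in EC50 panel header: ",
         paste(unique(universe[duplicated(universe)]), collapse = ", "))
  drug_ids <- trimws(tab[[1]])
  if (anyDuplicated(drug_ids))
    stop("duplicate drug id(s) in EC50 panel: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  profiles <- vector("list", length(drug_ids))
  names(profiles) <- drug_ids
  for (i in seq_along(drug_ids)) {
    cells <- trimws(unlist(tab[i, -1], use.names = FALSE))
    filled <- !is.na(cells) & nzchar(cells)
    vals <- suppressWarnings(as.numeric(cells[filled]))
    bad <- which(is.na(vals) | vals <= 0)
    if (length(bad)) {
      j <- which(filled)[bad[1]]
      stop(sprintf("EC50 panel: non-positive or non-numeric cell '%s' (drug '%s', target '%s')",
                   cells[filled][bad[1]], drug_ids[i], universe[j]))
    }
    names(vals) <- universe[filled]
    profiles[[i]] <- vals
  }
  list(universe = universe, profiles = profiles)
}

#' Write a drug x target EC50 panel
#'
#' Inverse of [read_ec50_panel()]; absent interactions become empty cells.
#'
#' @param panel list with `universe` and `profiles` as returned by
#'   [read_ec50_panel()].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_ec50_panel <- function(panel, path, sep = "\t") {
  uni <- panel$universe
  rows <- vapply(names(panel$profiles), function(d) {
    e <- panel$profiles[[d]]
    cells <- rep("", length(uni))
    cells[match(names(e), uni)] <- format(e, trim = TRUE, digits = 15)
    paste(c(d, cells), collapse = sep)
  }, character(1))
  writeLines(c(paste(c("drug", uni), collapse = sep), rows), path)
  invisible(path)
}

#' Read a per-culture IC50 table
#'
#' Rows are drugs (first column = drug id), remaining columns are tumor
#' cultures.  IC50 values are in nM.  A cell that is empty, equals the
#' sentinel token (default `"NR"`), or starts with `">"` encodes an IC50
#' that was not reached within the screened dose range; such drugs receive
#' `NA` in the returned vector and are later scored 0.
#'
#' @param path path to the delimited file (TSV/CSV auto-detected).
#' @param culture name of the culture column to extract.
#' @param sep optional explicit separator.
#' @param sentinel token marking a not-reached IC50 (besides empty / ">x").
#' @return named numeric vector drug id -> IC50 (nM), `NA` = not reached.
#' @export
read_ic50_table <- function(path, culture, sep = NULL, sentinel = "NR") {
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  cultures <- colnames(tab)[-1]
  if (!culture %in% cultures)
    stop(sprintf("culture '%s' not found; available cultures: %s",
                 culture, paste(cultures, collapse = ", ")))
  ids <- trimws(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate drug id(s) in IC50 table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- trimws(tab[[culture]])
  not_reached <- is.na(cells) | !nzchar(cells) | cells == sentinel |
    startsWith(cells, ">")
  vals <- rep(NA_real_, length(cells))
  vals[!not_reached] <- suppressWarnings(as.numeric(cells[!not_reached]))
  bad <- which(!not_reached & (is.na(vals) | vals <= 0))
  if (length(bad))
    stop(sprintf("IC50 table: non-positive or non-numeric cell '%s' (drug '%s', culture '%s')",
                 cells[bad[1]], ids[bad[1]], culture))
  names(vals) <- ids
  vals
}

#' Read a dosing table (drug id, Cmax, MaxDose)
#'
#' Columns `drug`, `cmax`, `maxdose` (nM); column order free, names matched
#' case-insensitively.  A missing/empty `cmax` falls back to `maxdose / 10`
#' with a warning, since the sensitivity scoring function needs an anchor
#' for the maximum clinically achievable dose.
#'
#' @param path path to the delimited file.
#' @param sep optional explicit separator.
#' @return data.frame with columns `drug`, `cmax`, `maxdose`.
#' @export
read_dosing_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  nm <- tolower(colnames(tab))
  need <- c("drug", "cmax", "maxdose")
  if (!all(need %in% nm))
    stop("dosing table must have columns drug, cmax, maxdose")
  drug <- trimws(tab[[which(nm == "drug")[1]]])
  cmax <- suppressWarnings(as.numeric(tab[[which(nm == "cmax")[1]]]))
  maxdose <- suppressWarnings(as.numeric(tab[[which(nm == "maxdose")[1]]]))
  if (any(is.na(maxdose) | maxdose <= 0))
    stop("dosing table: maxdose must be a positive number for every drug")
  miss <- is.na(cmax)
  if (any(miss)) {
    warning("dosing table: missing cmax for ",
            paste(drug[miss], collapse = ", "),
            "; falling back to maxdose/10")
    cmax[miss] <- maxdose[miss] / 10
  }
  if (any(cmax <= 0)) stop("dosing table: cmax must be positive")
  data.frame(drug = drug, cmax = cmax, maxdose = maxdose,
             stringsAsFactors = FALSE)
}

#' Assemble a screen dataset from panel, IC50 and dosing data
#'
#' Drugs present in the IC50 table but absent from the EC50 panel (or vice
#' versa) are dropped with a warning: a drug without both an interaction
#' profile and a measured response cannot inform target selection.
#'
#' @param panel list as from [read_ec50_panel()].
#' @param ic50 named numeric vector as from [read_ic50_table()] (`NA` = IC50
#'   not reached).
#' @param dosing data.frame as from [read_dosing_table()].
#' @param culture_id label carried through reports.
#' @return object of class `screen_dataset`: list with `universe`,
#'   `drugs` (data.frame drug/ic50/cmax/maxdose), `profiles`, `culture_id`.
#' @export
screen_dataset <- function(panel, ic50, dosing, culture_id = "culture") {
  ids <- intersect(names(panel$profiles), names(ic50))
  missing_panel <- setdiff(names(ic50), names(panel$profiles))
  missing_ic50 <- setdiff(names(panel$profiles), names(ic50))
  if (length(missing_panel))
    warning("drug(s) without an EC50 profile excluded from screen: ",
            paste(missing_panel, collapse = ", "))
  if (length(missing_ic50))
    warning("drug(s) without an IC50 measurement excluded from screen: ",
            paste(missing_ic50, collapse = ", "))
  if (length(ids) < 1L) stop("no drug has both an EC50 profile and an IC50")
  di <- match(ids, dosing$drug)
  if (anyNA(di))
    stop("dosing information missing for drug(s): ",
         paste(ids[is.na(di)], collapse = ", "))
  structure(list(
    universe = panel$universe,
    drugs = data.frame(drug = ids, ic50 = unname(ic50[ids]),
                       cmax = dosing$cmax[di], maxdose = dosing$maxdose[di],
                       stringsAsFactors = FALSE),
    profiles = panel$profiles[ids],
    culture_id = culture_id), class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("screen_dataset '%s': %d drugs x %d targets (%d IC50 not reached)\n",
              x$culture_id, nrow(x$drugs), length(x$universe),
              sum(is.na(x$drugs$ic50))))
  invisible(x)
}

# ---- JSON artifacts ---------------------------------------------------------

#' Write a Target Inhibition Map to versioned JSON
#'
#' Known combinations are emitted sorted by pattern so the output is
#' byte-identical across runs.
#'
#' @param tim object of class `tim` (see [build_tim()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tim_json <- function(tim, path) {
  ord <- order(as.integer(names(tim$known)))
  obj <- list(
    format = "timkit/tim",
    version = 1L,
    targets = tim$targets,
    discount = tim$discount,
    weights = tim$weights,
    known = lapply(ord, function(i) list(
      pattern = pattern_to_string(as.integer(names(tim$known))[i], tim$nT),
      value = unname(tim$known[[i]]))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Target Inhibition Map from JSON
#' @param path path written by [write_tim_json()].
#' @return object of class `tim`.
#' @export
read_tim_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "timkit/tim"))
    stop("not a timkit TIM JSON file: ", path)
  targets <- unlist(obj$targets)
  pats <- vapply(obj$known, function(e) string_to_pattern(e$pattern), integer(1))
  vals <- vapply(obj$known, function(e) as.numeric(e$value), numeric(1))
  build_tim(pats, vals, targets, discount = obj$discount,
            weights = unlist(obj$weights))
}

#' Write a TIM circuit to versioned JSON
#' @param circuit object of class `tim_circuit` (see [group_blocks()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circuit_json <- function(circuit, path) {
  obj <- list(
    format = "timkit/circuit",
    version = 1L,
    targets = circuit$targets,
    blocks = lapply(circuit$blocks, function(b) lapply(b, as.list)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a TIM circuit from JSON
#' @param path path written by [write_circuit_json()].
#' @return object of class `tim_circuit`.
#' @export
read_circuit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "timkit/circuit"))
    stop("not a timkit circuit JSON file: ", path)
  structure(list(
    targets = unlist(obj$targets),
    blocks = lapply(obj$blocks, function(b)
      lapply(b, function(l) unlist(lapply(l, as.character))))),
    class = "tim_circuit")
}
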