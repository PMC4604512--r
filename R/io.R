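#' Read a Mascot Generic Format (MGF) file
#'
#' Every `BEGIN IONS` block yields one [Spectrum-class]. `PEPMASS` and
#' `CHARGE` headers are parsed; peaks are sorted by m/z. Blocks without a
#' `PEPMASS` are skipped with a warning and counted in the `"skipped"`
#' attribute of the returned list. A missing `CHARGE` defaults to 2+ (the
#' most common tryptic precursor); the default is logged via `message()`.
#'
#' @param path path to an MGF file.
#' @return list of [Spectrum-class] objects, with attribute `skipped`.
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  out <- vector("list", length(starts))
  skipped <- 0L
  kept <- 0L
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    params <- block[hdr]
    key <- toupper(sub("=.*", "", params))
    val <- sub("^[^=]*=", "", params)
    if (!"PEPMASS" %in% key) {
      warning("MGF block ", k, " has no PEPMASS; skipped", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    pepmass <- suppressWarnings(
      as.numeric(strsplit(trimws(val[match("PEPMASS", key)]), "[ \t]+")[[1]][1]))
    if (is.na(pepmass)) {
      warning("MGF block ", k, " has unparseable PEPMASS; skipped",
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    if ("CHARGE" %in% key) {
      ch <- val[match("CHARGE", key)]
      z <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch)))
      if (is.na(z) || z < 1L) z <- 2L
    } else {
      message("MGF block ", k, ": no CHARGE, defaulting to 2+")
      z <- 2L
    }
    id <- if ("TITLE" %in% key) trimws(val[match("TITLE", key)]) else
      sprintf("index=%d", k)
    pk <- block[!hdr]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), function(f)
        suppressWarnings(as.numeric(f[1:2]))))
      ok <- stats::complete.cases(m)
      mzv <- m[ok, 1]
      inv <- m[ok, 2]
    } else {
      mzv <- numeric()
      inv <- numeric()
    }
    kept <- kept + 1L
    out[[kept]] <- Spectrum(mzv, inv, pepmass, z, id)
  }
  out <- out[seq_len(kept)]
  attr(out, "skipped") <- skipped
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", spectrumId(sp)),
      sprintf("PEPMASS=%.6f", precursorMz(sp)),
      sprintf("CHARGE=%d+", precursorCharge(sp)),
      sprintf("%.5f %.4f", peakMz(sp), peakIntensity(sp)),
      "END IONS"), con)
  }
  invisible(path)
}

#' Read an annotated spectral library in NIST MSP format
#'
#' Parses `Name: <peptide>/<charge>` entries into ([Spectrum-class],
#' [Peptide-class]) pairs. Entries whose peptide carries an unsupported
#' modification, or whose `Name` line cannot be parsed, are skipped with a
#' warning and counted in the `skipped` attribute. The precursor m/z is
#' taken from a `Comment: ... Parent=<mz>` field when present, otherwise
#' computed from the annotated peptide mass and charge.
#'
#' @param path path to an MSP file.
#' @param massTable residue mass table used to resolve the annotations.
#' @return list of `list(spectrum =, peptide =)` pairs, with attribute
#'   `skipped`.
#' @export
readMsp <- function(path, massTable = residueMassTable()) {
  if (!file.exists(path)) stop("cannot read MSP file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^Name:", lines)
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  kept <- 0L
  skipped <- 0L
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    name <- trimws(sub("^Name:", "", block[1L]))
    m <- regmatches(name, regexec("^(.+)/([0-9]+)\\s*$", name))[[1]]
    if (length(m) != 3L) {
      warning("MSP entry ", k, ": unparseable Name '", name, "'; skipped",
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    pep <- tryCatch(parsePeptide(m[2L], massTable),
                    treeDenovo_unsupported_mod = function(e) NULL,
                    error = function(e) NULL)
    if (is.null(pep)) {
      skipped <- skipped + 1L
      next
    }
    z <- as.integer(m[3L])
    parent <- NA_real_
    cm <- grep("^Comment:", block, value = TRUE)
    if (length(cm)) {
      pm <- regmatches(cm[1L], regexec("Parent=([0-9.]+)", cm[1L]))[[1]]
      if (length(pm) == 2L) parent <- as.numeric(pm[2L])
    }
    if (is.na(parent)) parent <- (peptideMass(pep) + z * PROTON_MASS) / z
    npk <- grep("^Num [Pp]eaks:", block)
    mzv <- numeric(); inv <- numeric()
    if (length(npk)) {
      pk <- block[-seq_len(npk[1L])]
      pk <- pk[nzchar(trimws(pk))]
      if (length(pk)) {
        mat <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"),
                                     function(f)
                                       suppressWarnings(as.numeric(f[1:2]))))
        ok <- stats::complete.cases(mat)
        mzv <- mat[ok, 1]
        inv <- mat[ok, 2]
      }
    }
    kept <- kept + 1L
    out[[kept]] <- list(
      spectrum = Spectrum(mzv, inv, parent, z, sprintf("msp=%d", k)),
      peptide = pep)
  }
  out <- out[seq_len(kept)]
  attr(out, "skipped") <- skipped
  out
}

#' Write an annotated library in NIST MSP format
#'
#' Oxidized Met is written as `M(O)`; carbamidomethyl Cys is implicit in
#' the `C` symbol (fixed modification).
#'
#' @param records list of `list(spectrum =, peptide =)` pairs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMsp <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    sp <- r$spectrum
    seqstr <- paste(sub("^m$", "M(O)", residues(r$peptide)), collapse = "")
    writeLines(c(
      sprintf("Name: %s/%d", seqstr, precursorCharge(sp)),
      sprintf("Comment: Parent=%.6f", precursorMz(sp)),
      sprintf("Num peaks: %d", peakCount(sp)),
      sprintf("%.5f\t%.4f", peakMz(sp), peakIntensity(sp)),
      ""), con)
  }
  invisible(path)
}

#' Write de novo results to a TSV file
#'
#' Columns: `spectrum_id`, `peptide`, `aggregate_score`, and the per-residue
#' integer scores (0-100) comma-joined. Empty results give an empty peptide
#' field.
#'
#' @param results list of [DeNovoResult-class] objects.
#' @param ids spectrum identifiers (same length as `results`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultTsv <- function(results, ids, path) {
  stopifnot(length(results) == length(ids))
  df <- data.frame(
    spectrum_id = as.character(ids),
    peptide = vapply(results, function(r)
      if (isEmptyResult(r)) "" else peptideString(resultPeptide(r)),
      character(1)),
    aggregate_score = vapply(results, function(r)
      if (isEmptyResult(r)) NA_real_ else aggregateScore(r), numeric(1)),
    residue_scores = vapply(results, function(r)
      if (isEmptyResult(r)) "" else
        paste(residueScores(r), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth PSM table
#'
#' Expects a TSV with columns `spectrum_id`, `peptide`, `charge`.
#'
#' @param path input path.
#' @param massTable residue mass table.
#' @return data.frame with an extra list-column `peptideObj`.
#' @export
readTruthTsv <- function(path, massTable = residueMassTable()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("spectrum_id", "peptide", "charge")
  if (!all(need %in% names(df))) {
    stop("truth TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$peptideObj <- lapply(df$peptide, parsePeptide, massTable = massTable)
  df
}
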