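#' Write a run to the JSON-lines interchange format
#'
#' One JSON object per line: a `header` record carrying schema and metadata,
#' then one `ms1` record per scan and one `ms2` record per spectrum, in
#' retention-time order. The format is plain text, versioned
#' (`palmap-run/1`), and round-trips exactly through [read_run_jsonl()].
#'
#' @param run an `annotated_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_jsonl <- function(run, path) {
  stopifnot(inherits(run, "annotated_run"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(list(type = "header"), run$metadata),
                              auto_unbox = TRUE, digits = NA), con)
  for (s in run$ms1_scans)
    writeLines(jsonlite::toJSON(list(type = "ms1", rt = s$rt, mz = s$mz,
                                     intensity = s$intensity),
                                auto_unbox = TRUE, digits = NA), con)
  for (s in run$ms2_spectra)
    writeLines(jsonlite::toJSON(list(type = "ms2",
                                     precursor_mz = s$precursor_mz,
                                     precursor_charge = s$precursor_charge,
                                     rt = s$rt, mz = s$mz,
                                     intensity = s$intensity),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Read a run from the JSON-lines interchange format
#'
#' @param path file written by [write_run_jsonl()].
#' @return an `annotated_run`.
#' @export
read_run_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty run file")
  recs <- lapply(lines, jsonlite::fromJSON)
  types <- vapply(recs, `[[`, character(1), "type")
  if (types[1] != "header") stop("missing header record")
  meta <- recs[[1]]; meta$type <- NULL
  ms1 <- lapply(recs[types == "ms1"], function(r)
    list(rt = r$rt, mz = as.numeric(r$mz), intensity = as.numeric(r$intensity)))
  ms2 <- lapply(recs[types == "ms2"], function(r)
    list(precursor_mz = r$precursor_mz, precursor_charge = r$precursor_charge,
         rt = r$rt, mz = as.numeric(r$mz), intensity = as.numeric(r$intensity)))
  structure(list(ms1_scans = ms1, ms2_spectra = ms2, metadata = meta),
            class = "annotated_run")
}

#' Import an mzML file into the run container
#'
#' Maps centroided mzML spectra onto the `annotated_run` container used by
#' the rest of the pipeline. Requires the Bioconductor `mzR` package.
#'
#' @param path mzML file.
#' @return an `annotated_run`.
#' @export
read_run_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML import requires the 'mzR' package")
  h <- NULL
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  h <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  ms1 <- list(); ms2 <- list()
  for (i in seq_len(nrow(h))) {
    p <- pk[[i]]
    if (h$msLevel[i] == 1L) {
      ms1[[length(ms1) + 1L]] <- list(rt = h$retentionTime[i],
                                      mz = p[, 1], intensity = p[, 2])
    } else {
      ms2[[length(ms2) + 1L]] <- list(precursor_mz = h$precursorMZ[i],
                                      precursor_charge = h$precursorCharge[i],
                                      rt = h$retentionTime[i],
                                      mz = p[, 1], intensity = p[, 2])
    }
  }
  structure(list(ms1_scans = ms1, ms2_spectra = ms2,
                 metadata = list(schema = "palmap-run/1", source = basename(path))),
            class = "annotated_run")
}

#' Read protein sequences from FASTA
#'
#' Headers may carry an `offset=<n>` token giving the residue number of the
#' first character (defaults to 1), preserving native numbering for excised
#' segments.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named list of [protein_sequence].
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- list()
  for (i in seq_along(aa)) {
    header <- names(aa)[i]
    off <- 1L
    m <- regmatches(header, regexpr("offset=[0-9]+", header))
    if (length(m) && nzchar(m)) off <- as.integer(sub("offset=", "", m))
    id <- strsplit(header, "\\s+")[[1]][1]
    out[[id]] <- protein_sequence(id, as.character(aa[[i]]), off)
  }
  out
}
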