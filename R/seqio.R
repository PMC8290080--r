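## FASTA input/output, six-frame translation and report writing.
##
## Sequence records travel as a plain data.frame (`id`, `alphabet`,
## `residues`); FASTA parsing and codon translation are delegated to
## Biostrings. Internal coordinates are 0-based half-open; every report is
## 1-based inclusive and says so in its header.

validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "alphabet", "residues") %in% names(records)))
  if (anyDuplicated(records$id))
    stop("duplicate sequence id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (any(!nzchar(records$residues)))
    stop("empty sequence record(s): ",
         paste(records$id[!nzchar(records$residues)], collapse = ", "))
  for (i in seq_len(nrow(records))) {
    res <- records$residues[i]
    ok <- if (records$alphabet[i] == "nucleotide") {
      !grepl("[^ACGTN]", res)
    } else {
      !grepl("[^ARNDCQEGHILKMFPSTWYVX*]", res)
    }
    if (!ok)
      stop("record '", records$id[i], "': residues outside the ",
           records$alphabet[i], " alphabet")
  }
  invisible(records)
}

#' Read a FASTA file into a sequence-record table
#'
#' @param path FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`; records violating the
#'   alphabet (nucleotide: A,C,G,T,N; protein: 20 canonical letters plus X
#'   and `*`) are rejected with an error naming the record.
#' @return data.frame with columns `id`, `alphabet`, `residues`, rows in
#'   file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e)))
  if (!length(set)) stop("no records in '", path, "'")
  records <- data.frame(
    id = sub("\\s.*$", "", names(set)),
    alphabet = alphabet,
    residues = toupper(as.character(set)),
    stringsAsFactors = FALSE
  )
  validate_records(records)
}

#' Write sequence records as FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path output file.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    res <- records$residues[i]
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))),
               con)
  }
  invisible(path)
}

#' Translate a nucleotide record in all six reading frames
#'
#' Frames +1..+3 read the given strand from offsets 0..2; frames -1..-3 read
#' the reverse complement likewise. Trailing partial codons are dropped;
#' stop codons are rendered as `*`; codons containing N translate to `X`.
#'
#' @param record one row of a nucleotide record table (or a list with `id`
#'   and `residues`).
#' @param table genetic code id as in [Biostrings::getGeneticCode()]
#'   (default `"1"`, the standard code).
#' @return data.frame of six protein records, ids suffixed `_frame+1` ..
#'   `_frame-3`, with a `frame` column.
#' @export
six_frame_translate <- function(record, table = "1") {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  if (!is.null(record$alphabet) && record$alphabet != "nucleotide")
    stop("six_frame_translate() expects a nucleotide record")
  res <- record$residues
  if (grepl("[^ACGTN]", res))
    stop("six_frame_translate() expects a nucleotide record")
  if (nchar(res) < 3L) stop("sequence shorter than one codon")
  code <- Biostrings::getGeneticCode(table)
  fwd <- Biostrings::DNAString(res)
  rev <- Biostrings::reverseComplement(fwd)
  one_frame <- function(dna, offset) {
    n <- length(dna) - offset
    n <- n - n %% 3L
    if (n < 3L) return("")
    sub <- Biostrings::subseq(dna, start = offset + 1L, width = n)
    as.character(Biostrings::translate(sub, genetic.code = code,
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
  }
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  prots <- c(vapply(0:2, function(o) one_frame(fwd, o), character(1)),
             vapply(0:2, function(o) one_frame(rev, o), character(1)))
  data.frame(
    id = paste0(record$id, "_frame", ifelse(frames > 0, "+", ""), frames),
    alphabet = "protein",
    residues = prots,
    frame = frames,
    stringsAsFactors = FALSE
  )
}

#' Write a peptide report for a catalog
#'
#' One row per mature peptide: precursor id, species, segment interval
#' (1-based inclusive on the precursor), precursor classification, amidation,
#' average mass, pI, length class, fusion flag and Cys count.
#'
#' @param catalog an `lp_catalog` (see [new_catalog()]).
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(catalog, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- catalog_peptide_table(catalog)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# venomLP peptide report; coordinates 1-based inclusive", con)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(coordinates = "1-based inclusive", peptides = tab),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a JSON peptide report
#'
#' @param path file written by [write_report()] with `format = "json"`.
#' @return the peptide table as a data.frame.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$peptides
}

## Flat per-peptide table over all species and precursor models of a catalog.
catalog_peptide_table <- function(catalog) {
  rows <- list()
  for (sp in catalog$species) {
    for (model in sp$models) {
      if (inherits(model, "lp_no_architecture")) next
      for (pep in model$peptides) {
        iv <- interval_onebased(pep$interval)
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp$id,
          precursor_id = model$id,
          start = iv[["start"]],
          end = iv[["end"]],
          sequence = pep$sequence,
          precursor_type = model$ptype,
          amidated = pep$amidated,
          average_mass = round(average_mass(pep$sequence, pep$amidated), 2),
          pi = round(isoelectric_point(pep$sequence, pep$amidated), 2),
          length_class = length_class(pep$sequence),
          fusion_flag = pep$fusion_flag,
          cys_count = pep$cys_count,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(
      species = character(), precursor_id = character(), start = integer(),
      end = integer(), sequence = character(), precursor_type = character(),
      amidated = logical(), average_mass = numeric(), pi = numeric(),
      length_class = character(), fusion_flag = character(),
      cys_count = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
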