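# Coordinate convention: everything in memory is 0-based half-open.
# On-disk origin tables are 1-based inclusive (oriDB convention); bedGraph
# is already 0-based half-open.

#' Read a genome from a FASTA file
#'
#' Sequences are validated to contain only A, C, G, T and N.  Sequence names
#' are truncated at the first whitespace and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome)
  genome
}

#' @rdname read_genome
#' @param genome A `DNAStringSet` (or named character vector of sequences).
#' @export
validate_genome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (length(genome) == 0L) stop("genome contains no sequences")
  if (is.null(names(genome)) || anyDuplicated(names(genome))) {
    stop("chromosome names must be present and unique")
  }
  if (any(Biostrings::width(genome) == 0L)) stop("empty sequence in genome")
  freq <- Biostrings::alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, !colnames(freq) %in% allowed, drop = FALSE])
  if (any(bad > 0)) {
    stop("sequences restricted to alphabet {A,C,G,T,N}; offending: ",
         paste(names(genome)[bad > 0], collapse = ", "))
  }
  invisible(genome)
}

#' Read an origin annotation table
#'
#' The on-disk table is tab- or comma-delimited with a header and carries
#' 1-based inclusive coordinates; in memory, coordinates are 0-based
#' half-open.  Required columns: `chrom`, `start`, `end`, `name`, `status`
#' (one of `confirmed`, `likely`, `dubious`).  Optional columns: `acs_pos`
#' (1-based position of the T-rich-strand start of the extended ACS),
#' `acs_strand` (`+`/`-`), and `telomeric_core_x` (logical exclusion flag
#' for core-X telomere-associated origins).
#'
#' @param path Path to the delimited file.
#' @return A data frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open), `status`, `acs_pos` (0-based or `NA`),
#'   `acs_strand`, `telomeric_core_x`.
#' @export
read_origin_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  required <- c("chrom", "start", "end", "name", "status")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("origin table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(empty_origin_table())
  }
  if (!is.numeric(df$start) || !is.numeric(df$end)) {
    stop("origin table coordinates must be numeric")
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L) {
    stop("malformed coordinates (start >= end) at data line(s): ",
         paste(bad, collapse = ", "))
  }
  dup <- df$name[duplicated(df$name)]
  if (length(dup) > 0L) {
    stop("duplicate origin names: ", paste(unique(dup), collapse = ", "))
  }
  known <- c("confirmed", "likely", "dubious")
  bad_status <- which(!df$status %in% known)
  if (length(bad_status) > 0L) {
    stop("unknown origin status at data line(s): ",
         paste(bad_status, collapse = ", "))
  }
  out <- data.frame(
    name = as.character(df$name),
    chrom = as.character(df$chrom),
    start = as.integer(df$start) - 1L,   # 1-based inclusive -> 0-based
    end = as.integer(df$end),            # inclusive end == half-open end
    status = df$status,
    acs_pos = if ("acs_pos" %in% names(df)) {
      as.integer(df$acs_pos) - 1L
    } else NA_integer_,
    acs_strand = if ("acs_strand" %in% names(df)) {
      as.character(df$acs_strand)
    } else NA_character_,
    telomeric_core_x = if ("telomeric_core_x" %in% names(df)) {
      as.logical(df$telomeric_core_x)
    } else FALSE,
    stringsAsFactors = FALSE
  )
  has_acs <- !is.na(out$acs_pos)
  off <- has_acs &
    (out$acs_pos < out$start - 1000L | out$acs_pos > out$end + 1000L)
  if (any(off)) {
    stop("acs_pos outside [start-1000, end+1000] for: ",
         paste(out$name[off], collapse = ", "))
  }
  if (any(has_acs & !out$acs_strand[has_acs] %in% c("+", "-"))) {
    stop("acs_strand must be '+' or '-' where acs_pos is present")
  }
  out
}

empty_origin_table <- function() {
  data.frame(name = character(), chrom = character(),
             start = integer(), end = integer(), status = character(),
             acs_pos = integer(), acs_strand = character(),
             telomeric_core_x = logical(), stringsAsFactors = FALSE)
}

#' Write an origin annotation table
#'
#' Inverse of [read_origin_table()]: converts internal 0-based half-open
#' coordinates back to 1-based inclusive on disk.
#'
#' @param origins Origin data frame as returned by [read_origin_table()].
#' @param path Output path (tab-delimited).
#' @export
write_origin_table <- function(origins, path) {
  out <- origins
  out$start <- out$start + 1L
  if (!is.null(out$acs_pos)) out$acs_pos <- out$acs_pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a probe signal track
#'
#' A probe track stores, per chromosome, ordered probe midpoints (bp) and
#' log2-ratio values (log2(Cy5/Cy3)) for one experimental condition.
#' Midpoints must be strictly increasing within a chromosome and values
#' finite.
#'
#' @param chroms Named list; each element a data frame (or list) with
#'   numeric `mid` and `value`.
#' @param condition Condition label, e.g. `"ORC2"`, `"orc2-1"`,
#'   `"gEMSA_0.3nM"`.
#' @return An object of class `probe_track`.
#' @export
probe_track <- function(chroms, condition = "track") {
  stopifnot(is.list(chroms), length(names(chroms)) == length(chroms))
  chroms <- lapply(chroms, function(ch) {
    data.frame(mid = as.numeric(ch$mid), value = as.numeric(ch$value))
  })
  obj <- structure(list(condition = condition, chroms = chroms),
                   class = "probe_track")
  validate_probe_track(obj)
  obj
}

validate_probe_track <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  for (chrom in names(track$chroms)) {
    ch <- track$chroms[[chrom]]
    if (anyNA(ch$mid) || anyNA(ch$value) || any(!is.finite(ch$value))) {
      stop("non-finite probe data on ", chrom)
    }
    if (is.unsorted(ch$mid, strictly = TRUE)) {
      if (anyDuplicated(ch$mid)) {
        stop("duplicate probe midpoints on ", chrom)
      }
      stop("probe midpoints not strictly increasing on ", chrom)
    }
  }
  invisible(track)
}

#' @export
print.probe_track <- function(x, ...) {
  n <- sum(vapply(x$chroms, nrow, integer(1)))
  cat("probe_track '", x$condition, "': ", n, " probes on ",
      length(x$chroms), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' All probe values of a track as one vector
#' @param track A `probe_track`.
#' @return Numeric vector of all log2-ratio values.
#' @export
track_values <- function(track) {
  unlist(lapply(track$chroms, `[[`, "value"), use.names = FALSE)
}

#' Read a probe track from a bedGraph file
#'
#' The 4-column bedGraph dialect (chrom, start, end, value; 0-based
#' half-open) is read with \pkg{rtracklayer}.  The probe position is the
#' interval midpoint, `floor((start+end)/2)`.  Overlapping probes are
#' permitted; identical midpoints are rejected.  Unsorted input is sorted
#' silently with a message.
#'
#' @param path Path to a bedGraph file.
#' @param condition Condition label attached to the track.
#' @return A [probe_track()].
#' @export
read_probe_track <- function(path, condition = basename(path)) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (anyNA(gr$score)) stop("non-numeric value in bedGraph ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # import() yields 1-based starts; midpoint of [start0, end) is
    # floor((start0 + end) / 2)
    mid = floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2),
    value = gr$score
  )
  chroms <- split(df[c("mid", "value")], df$chrom)
  chroms <- lapply(chroms, function(ch) {
    if (anyDuplicated(ch$mid)) {
      stop("identical probe midpoints in ", path)
    }
    if (is.unsorted(ch$mid)) {
      message("unsorted probes in ", path, "; sorting")
      ch <- ch[order(ch$mid), ]
    }
    rownames(ch) <- NULL
    ch
  })
  probe_track(chroms, condition = condition)
}

#' Write a probe track to a bedGraph file
#'
#' Each probe is written as a 1-bp interval at its midpoint, so that a
#' read/write round trip is the identity.
#'
#' @param track A [probe_track()].
#' @param path Output path.
#' @export
write_probe_track <- function(track, path) {
  chrom <- rep(names(track$chroms),
               vapply(track$chroms, nrow, integer(1)))
  mid <- unlist(lapply(track$chroms, `[[`, "mid"), use.names = FALSE)
  value <- track_values(track)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = mid + 1, end = mid + 1), score = value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a per-origin result table as CSV
#'
#' One row per origin, stable column order, `NA` encoded as the empty
#' string except in columns listed in `nd_columns`, where `NA` marks a
#' censored ("not determinable") estimate and is written as `"ND"`.
#'
#' @param table Data frame keyed by an `origin` column.
#' @param path Output CSV path.
#' @param nd_columns Character vector of column names whose `NA`s encode
#'   censored Kd-like values.
#' @export
write_result_table <- function(table, path, nd_columns = "kd") {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("result table must be a non-empty data frame")
  }
  if (!"origin" %in% names(table)) stop("result table must have an 'origin' column")
  if (anyDuplicated(table$origin)) stop("one row per origin required")
  out <- table
  for (col in intersect(nd_columns, names(out))) {
    v <- as.character(out[[col]])
    v[is.na(out[[col]])] <- "ND"
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @inheritParams write_result_table
#' @param path CSV path.
#' @return Data frame; `"ND"` entries in `nd_columns` become `NA` and the
#'   column is numeric.
#' @export
read_result_table <- function(path, nd_columns = "kd") {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(nd_columns, names(df))) {
    v <- df[[col]]
    v[v == "ND"] <- NA
    df[[col]] <- as.numeric(v)
  }
  df
}
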