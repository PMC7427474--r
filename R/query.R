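# Query surface: browse and filter the core tables, render marker detail
# views, export FASTA, and construct candidate amplicon intervals.

#' Parse a genomic region string
#'
#' Accepted forms: `"chr5"` (whole chromosome), `"chr5:1000000"` (from a
#' position to the chromosome end), `"chr5:1000000-2000000"`. Coordinates
#' are 1-based and inclusive at both ends; a bare `"5"` is normalized to
#' `"chr5"`.
#'
#' @param region region string.
#' @return List with `chrom`, `start`, `end` (`NA` when open-ended).
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^(chr)?([0-9]{1,2}|[XYM]|MT)(:([0-9]+)(-([0-9]+))?)?$", region))[[1]]
  if (!length(m)) stop("malformed region string: '", region, "'")
  start <- if (m[5] == "") NA_integer_ else as.integer(m[5])
  end <- if (m[7] == "") NA_integer_ else as.integer(m[7])
  if (!is.na(start) && start < 1) stop("region start must be >= 1")
  if (!is.na(start) && !is.na(end) && start > end) stop("region start exceeds end: '", region, "'")
  list(chrom = paste0("chr", m[3]), start = start, end = end)
}

#' Query markers by identifier, source, or genomic region
#'
#' With no selector and no region, returns the whole marker table in
#' coordinate order. A selector token is resolved in a fixed precedence
#' order: exact marker name, then third-party identifier (via the `idmap`
#' table), then variant rsID (via the `variantmap` table, falling back to a
#' scan of marker definitions -- an rsID shared by overlapping markers
#' returns all of them), then source label. A region selects markers whose
#' span intersects it. Results are stable under permutation of the table
#' rows: ordering is always (chromosome, start, name).
#'
#' @param db an `mhdb`.
#' @param selector identifier token (marker name, third-party ID, rsID, or
#'   source label), or `NULL`.
#' @param region region string (see [parse_region()]) or `NULL`.
#' @return Marker table rows (possibly empty; an empty result prints a
#'   not-found notice via `message()`).
#' @export
query_markers <- function(db, selector = NULL, region = NULL) {
  stopifnot(inherits(db, "mhdb"))
  mk <- sort_markers(db$markers)
  if (!is.null(selector)) {
    hits <- character(0)
    if (selector %in% mk$Name) {
      hits <- selector
    } else if (selector %in% db$idmap$ID) {
      hits <- db$idmap$Name[db$idmap$ID == selector]
    } else {
      rs <- split_csv(mk$RSIDs)
      by_rs <- mk$Name[vapply(rs, function(r) selector %in% r, logical(1))]
      by_map <- db$variantmap$Marker[db$variantmap$RSID == selector]
      hits <- unique(c(by_map, by_rs))
      if (!length(hits) && selector %in% mk$Source) {
        hits <- mk$Name[mk$Source == selector]
      }
    }
    mk <- mk[mk$Name %in% hits, , drop = FALSE]
  }
  if (!is.null(region)) {
    r <- if (is.character(region)) parse_region(region) else region
    sp <- marker_spans(mk)
    keep <- sp$Chrom == r$chrom &
      (is.na(r$end) | sp$Start <= r$end) &
      (is.na(r$start) | sp$End >= r$start)
    mk <- mk[keep, , drop = FALSE]
  }
  if (!nrow(mk)) {
    message("no markers found",
            if (!is.null(selector)) paste0(" for '", selector, "'") else "")
  }
  rownames(mk) <- NULL
  mk
}

#' Candidate amplicon interval for a marker
#'
#' Starts from the marker span extended by `delta` bases on each side. If
#' the result is shorter than `min_length`, both sides are extended as
#' evenly as possible (an odd surplus base goes to the right). The interval
#' is then clipped to `[1, chrom_length]`, shifting any clipped deficit to
#' the opposite side, so the final length is
#' `max(span + 2 * delta, min_length)` unless the chromosome itself is too
#' short.
#'
#' @param marker marker definition (see [as_marker()]).
#' @param delta flanking bases added to each side of the marker span.
#' @param min_length minimum amplicon length, in bp.
#' @param chrom_length chromosome length; bounds the interval.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @examples
#' m <- as_marker(list(name = "mh00XX-1", chrom = "chr1",
#'                     positions = c(1000, 1050), rsids = c("rs1", "rs2")))
#' amplicon_bounds(m, delta = 25, min_length = 0, chrom_length = 1e6)  # 975 1075
#' amplicon_bounds(m, delta = 0, min_length = 61, chrom_length = 1e6)  # 995 1055
#' @export
amplicon_bounds <- function(marker, delta = 10, min_length = 0, chrom_length) {
  marker <- as_marker(marker)
  stopifnot(delta >= 0, min_length >= 0, chrom_length >= max(marker$positions))
  s <- min(marker$positions) - delta
  e <- max(marker$positions) + delta
  len <- e - s + 1
  if (len < min_length) {
    need <- min_length - len
    s <- s - need %/% 2
    e <- e + need %/% 2 + need %% 2
  }
  if (s < 1) {
    e <- e + (1 - s)
    s <- 1
  }
  if (e > chrom_length) {
    s <- s - (e - chrom_length)
    e <- chrom_length
  }
  if (s < 1) s <- 1
  as.integer(c(s, e))
}

# Fetch the stored flanking sequence for a marker; NULL when absent.
marker_sequence <- function(db, name) {
  i <- match(name, db$sequences$Marker)
  if (is.na(i)) return(NULL)
  list(start = as.integer(db$sequences$Start[i]),
       seq = db$sequences$Sequence[i])
}

#' Amplicon view of a marker
#'
#' Combines the marker definition, its stored flanking sequence, the
#' amplicon interval from [amplicon_bounds()], the 0-based offsets of the
#' component variants within the amplicon sequence, and the haplotypes
#' observed in the frequency table. The amplicon is necessarily confined to
#' the stored sequence window, which acts as the addressable coordinate
#' range.
#'
#' @param db an `mhdb` with a populated `sequences` table.
#' @param name marker name.
#' @inheritParams amplicon_bounds
#' @return An object of class `mh_amplicon`: list with `marker`, `chrom`,
#'   `start`, `end`, `sequence`, `offsets` (0-based within `sequence`) and
#'   `haplotypes`.
#' @export
amplicon_view <- function(db, name, delta = 10, min_length = 0) {
  stopifnot(inherits(db, "mhdb"))
  def <- marker_def(db, name)
  sq <- marker_sequence(db, name)
  if (is.null(sq)) stop("no sequence stored for marker '", name, "'")
  win_len <- nchar(sq$seq)
  # translate to window-local coordinates and treat the window as the
  # addressable chromosome
  local <- def
  local$positions <- def$positions - sq$start + 1L
  stopifnot(all(local$positions >= 1), all(local$positions <= win_len))
  b <- amplicon_bounds(local, delta = delta, min_length = min_length,
                       chrom_length = win_len)
  seq <- substr(sq$seq, b[1], b[2])
  offsets <- local$positions - b[1]
  haps <- sort(unique(db$frequencies$Allele[db$frequencies$Marker == name]))
  structure(
    list(marker = name, chrom = def$chrom,
         start = sq$start + b[1] - 1L, end = sq$start + b[2] - 1L,
         sequence = seq, offsets = as.integer(offsets), haplotypes = haps),
    class = "mh_amplicon"
  )
}

wrap_seq <- function(seq, width = 80) {
  n <- nchar(seq)
  if (n == 0) return(character(0))
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Render a marker detail view
#'
#' A fixed-layout text block showing the marker name and source, each
#' component SNP's rsID and coordinate, the core span and its length, the
#' candidate amplicon sequence with component-SNP positions marked, and the
#' haplotypes observed at the marker. When no flanking sequence is stored
#' the sequence section is omitted with a warning.
#'
#' @inheritParams amplicon_view
#' @return A single string (the detail block).
#' @export
render_marker_detail <- function(db, name, delta = 10, min_length = 80) {
  stopifnot(inherits(db, "mhdb"))
  def <- marker_def(db, name)
  span_start <- min(def$positions)
  span_end <- max(def$positions)
  lines <- c(
    paste0(strrep("-", 70)),
    paste0(def$name, "    ", length(def$positions), "-SNP microhaplotype marker (source: ",
           def$source, ")"),
    paste0(strrep("-", 70)),
    paste0("Chromosome:  ", def$chrom),
    paste0("Core span:   ", def$chrom, ":", span_start, "-", span_end,
           " (", span_end - span_start + 1L, " bp)"),
    paste0("SNPs (", length(def$positions), "):"),
    paste0("  ", format(def$rsids, width = max(nchar(def$rsids))), "  ",
           def$chrom, ":", def$positions)
  )
  sq <- marker_sequence(db, name)
  if (is.null(sq)) {
    warning("no sequence stored for marker '", name, "'; detail emitted without sequence")
  } else {
    av <- amplicon_view(db, name, delta = delta, min_length = min_length)
    lines <- c(lines, "",
               paste0("Amplicon (", av$chrom, ":", av$start, "-", av$end, ", ",
                      nchar(av$sequence), " bp; delta=", delta,
                      ", min_length=", min_length, "):"))
    chunks <- wrap_seq(av$sequence, 70)
    marks <- rep(" ", nchar(av$sequence))
    marks[av$offsets + 1] <- "*"
    marks <- paste(marks, collapse = "")
    mchunks <- wrap_seq(marks, 70)
    for (i in seq_along(chunks)) {
      lines <- c(lines, chunks[i])
      if (grepl("*", mchunks[i], fixed = TRUE)) lines <- c(lines, sub(" +$", "", mchunks[i]))
    }
  }
  haps <- sort(unique(db$frequencies$Allele[db$frequencies$Marker == name]))
  lines <- c(lines, "",
             if (length(haps)) c(paste0("Observed haplotypes (", length(haps), "):"),
                                 paste0("  ", haps))
             else "Observed haplotypes: none observed",
             strrep("-", 70))
  paste(lines, collapse = "\n")
}

#' @export
print.mh_amplicon <- function(x, ...) {
  cat(">", x$marker, " ", x$chrom, ":", x$start, "-", x$end, "\n", sep = "")
  cat(wrap_seq(x$sequence, 80), sep = "\n")
  invisible(x)
}

#' Export markers as FASTA amplicon records
#'
#' One record per marker: the header carries the marker name, the amplicon
#' region, and the 0-based offsets of the component variants within the
#' sequence; the sequence is the amplicon interval's nucleotides, wrapped at
#' 80 columns. Markers without a stored sequence are skipped with a warning.
#'
#' @param db an `mhdb`.
#' @param names marker names (default: all markers with stored sequences).
#' @inheritParams amplicon_bounds
#' @return FASTA text as a single string (empty string for an empty list).
#' @export
markers_to_fasta <- function(db, names = NULL, delta = 10, min_length = 0) {
  stopifnot(inherits(db, "mhdb"))
  names <- names %||% db$markers$Name[db$markers$Name %in% db$sequences$Marker]
  recs <- character(0)
  for (nm in names) {
    if (is.null(marker_sequence(db, nm))) {
      warning("no sequence stored for marker '", nm, "'; skipped")
      next
    }
    av <- amplicon_view(db, nm, delta = delta, min_length = min_length)
    recs <- c(recs,
              paste0(">", av$marker, " ", av$chrom, ":", av$start, "-", av$end,
                     " variants=", paste(av$offsets, collapse = ",")),
              wrap_seq(av$sequence, 80))
  }
  if (!length(recs)) return("")
  paste0(paste(recs, collapse = "\n"), "\n")
}

#' Population detail summary
#'
#' For one population: the number of markers with at least one frequency
#' record, and the total number of distinct microhaplotypes observed
#' (frequency > 0) in the population sample.
#'
#' @param db an `mhdb`.
#' @param population population ID.
#' @return List with `population`, `name`, `n_markers`, `n_haplotypes`, or
#'   `NULL` (with a notice) when the population is unknown.
#' @export
population_detail <- function(db, population) {
  stopifnot(inherits(db, "mhdb"))
  i <- match(population, db$populations$ID)
  if (is.na(i)) {
    message("no population found for '", population, "'")
    return(NULL)
  }
  fq <- db$frequencies
  fq <- fq[fq$Population == population & fq$Frequency > 0, , drop = FALSE]
  list(population = population,
       name = db$populations$Name[i],
       n_markers = length(unique(fq$Marker)),
       n_haplotypes = nrow(unique(fq[, c("Marker", "Allele")])))
}

#' Query populations and frequencies
#'
#' `query_populations` filters the population table by ID, name, or source;
#' `query_frequencies` filters the frequency table by marker and/or
#' population. With no selector the full table is returned.
#'
#' @param db an `mhdb`.
#' @param selector population ID, name, or source label.
#' @return Table rows (possibly empty, with a not-found notice).
#' @export
query_populations <- function(db, selector = NULL) {
  pp <- db$populations
  if (!is.null(selector)) {
    pp <- pp[pp$ID == selector | pp$Name == selector | pp$Source == selector, , drop = FALSE]
  }
  if (!nrow(pp)) message("no populations found",
                         if (!is.null(selector)) paste0(" for '", selector, "'") else "")
  rownames(pp) <- NULL
  pp
}

#' @rdname query_populations
#' @param marker,population optional filters.
#' @export
query_frequencies <- function(db, marker = NULL, population = NULL) {
  fq <- sort_frequencies(db$frequencies)
  if (!is.null(marker)) fq <- fq[fq$Marker %in% marker, , drop = FALSE]
  if (!is.null(population)) fq <- fq[fq$Population %in% population, , drop = FALSE]
  if (!nrow(fq)) message("no frequency records found")
  rownames(fq) <- NULL
  fq
}
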