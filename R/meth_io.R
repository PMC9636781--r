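#' Read a genome from FASTA
#'
#' Loads a FASTA file into a named [Biostrings::DNAStringSet]. Sequences are
#' uppercased, `U` is mapped to `T`, and any other character outside
#' `{A,C,G,T,N}` is replaced by `N` with a warning. Coordinates throughout
#' the package are 1-based for cytosine records (CX-report convention) and
#' 0-based half-open for intervals (BED/bedGraph convention).
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet], one element per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA (no records): ", path)
  nm <- sub("\\s.*$", "", names(raw))
  if (any(nm == "")) stop("empty contig name in FASTA: ", path)
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("non-ACGTN characters in contig(s) ",
            paste(nm[bad], collapse = ", "), "; replaced by N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- nm
  g
}

# Accept a DNAStringSet or a named character vector; return named character.
genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    x <- as.character(genome)
  } else if (is.character(genome)) {
    x <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(x)) || any(names(x) == "")) stop("genome contigs must be named")
  if (anyDuplicated(names(x))) stop("duplicate contig names in genome")
  x
}

#' Construct a table of per-cytosine methylation records
#'
#' The central tabular type of the package: one row per strand-resolved
#' cytosine with methylated/unmethylated read counts and its trinucleotide
#' context. Positions are 1-based on the given contig; for minus-strand
#' records the context string reads 5'->3' on the minus strand.
#'
#' @param contig contig names.
#' @param pos 1-based positions.
#' @param strand `"+"` or `"-"`.
#' @param meth,unmeth non-negative read counts.
#' @param context trinucleotide context strings.
#' @return a `data.frame` with class `cytosine_report`.
#' @export
cytosine_report <- function(contig, pos, strand, meth, unmeth, context) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(meth < 0) || any(unmeth < 0)) stop("read counts must be non-negative")
  df <- data.frame(
    contig = as.character(contig), pos = as.integer(pos),
    strand = as.character(strand), meth = as.integer(meth),
    unmeth = as.integer(unmeth), context = as.character(context),
    stringsAsFactors = FALSE
  )
  class(df) <- c("cytosine_report", "data.frame")
  df
}

#' Read a per-cytosine methylation report
#'
#' Parses the 6-column CX-style TSV dialect (no header): contig,
#' position (1-based), strand (+/-), count_methylated, count_unmethylated,
#' trinucleotide_context. Malformed lines raise an error naming the line.
#'
#' @param path path to the TSV file.
#' @return a `cytosine_report` data frame, rows in file order.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(cytosine_report(character(0), integer(0), character(0),
                           integer(0), integer(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    stop("malformed cytosine report line ", which(nf != 6L)[1],
         ": expected 6 tab-separated columns, got ", nf[nf != 6L][1])
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 4]))
  unmeth <- suppressWarnings(as.integer(m[, 5]))
  bad_num <- which(is.na(pos) | is.na(meth) | is.na(unmeth) |
                     meth < 0 | unmeth < 0 | pos < 1)
  if (length(bad_num)) {
    stop("malformed cytosine report line ", bad_num[1],
         ": position/counts must be non-negative integers (position >= 1)")
  }
  bad_strand <- which(!(m[, 3] %in% c("+", "-")))
  if (length(bad_strand)) {
    stop("malformed cytosine report line ", bad_strand[1],
         ": strand must be '+' or '-', got '", m[bad_strand[1], 3], "'")
  }
  cytosine_report(m[, 1], pos, m[, 3], meth, unmeth, m[, 6])
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]; round-trips field-for-field.
#'
#' @param records a `cytosine_report` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  utils::write.table(
    records[, c("contig", "pos", "strand", "meth", "unmeth", "context")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Validate cytosine records against a genome
#'
#' Asserts that for every record the genome base at (contig, pos) is `C` on
#' the stated strand (i.e. `C` on the plus strand, `G` on the reference for
#' minus-strand records).
#'
#' @param records a `cytosine_report`.
#' @param genome a genome as from [read_genome()].
#' @return `TRUE` invisibly; errors on the first offending record.
#' @export
validate_cytosine_records <- function(records, genome) {
  g <- genome_chars(genome)
  unknown <- setdiff(unique(records$contig), names(g))
  if (length(unknown)) stop("records reference unknown contig(s): ",
                            paste(unknown, collapse = ", "))
  len <- nchar(g)[records$contig]
  oob <- which(records$pos < 1L | records$pos > len)
  if (length(oob)) {
    stop("record ", oob[1], " (", records$contig[oob[1]], ":",
         records$pos[oob[1]], ") is outside its contig")
  }
  base <- substring(g[records$contig], records$pos, records$pos)
  want <- ifelse(records$strand == "+", "C", "G")
  bad <- which(base != want)
  if (length(bad)) {
    stop("record ", bad[1], " (", records$contig[bad[1]], ":",
         records$pos[bad[1]], records$strand[bad[1]],
         ") does not sit on a cytosine (reference base ", base[bad[1]], ")")
  }
  invisible(TRUE)
}

#' Construct a binned methylation track
#'
#' @param contig,start,end bin coordinates (0-based half-open).
#' @param level pooled methylation level in `[0,1]`.
#' @param depth total read count pooled in the bin.
#' @return a `data.frame` with class `binned_track`, sorted by contig/start.
#' @export
binned_track <- function(contig, start, end, level, depth = NA_integer_) {
  depth <- rep(depth, length.out = length(contig))
  df <- data.frame(contig = as.character(contig), start = as.integer(start),
                   end = as.integer(end), level = as.numeric(level),
                   depth = as.integer(depth), stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("binned_track", "data.frame")
  df
}

#' Write a binned track as bedGraph
#'
#' Writes `contig  start  end  level` (0-based half-open) with levels
#' formatted to six decimals. Bins must be non-overlapping within a contig.
#'
#' @param track a `binned_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binned_track <- function(track, path) {
  if (nrow(track)) {
    sp <- split(track, track$contig)
    for (tr in sp) {
      tr <- tr[order(tr$start), ]
      if (any(tr$start[-1] < tr$end[-nrow(tr)])) {
        stop("overlapping bins on contig ", tr$contig[1])
      }
    }
    lines <- sprintf("%s\t%d\t%d\t%.6f", track$contig, track$start,
                     track$end, track$level)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file written by [write_binned_track()]
#'
#' @param path path to a 4-column bedGraph file.
#' @return a `binned_track` (depth unknown, `NA`).
#' @export
read_binned_track <- function(path) {
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  if (file.size(path) == 0L) {
    return(binned_track(character(0), integer(0), integer(0), numeric(0)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "level"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  binned_track(df$contig, df$start, df$end, df$level)
}

#' Construct an anchor set
#'
#' Anchors are strand-oriented reference points (e.g. transcription or
#' translation start sites) used by [aggregate_profile()]. Positions are
#' 0-based.
#'
#' @param contig,pos,strand,name anchor fields; `pos` 0-based.
#' @return a `data.frame` with class `anchor_set`.
#' @export
anchor_set <- function(contig, pos, strand, name = NULL) {
  if (!all(strand %in% c("+", "-"))) stop("anchor strand must be '+' or '-'")
  df <- data.frame(contig = as.character(contig), pos = as.integer(pos),
                   strand = as.character(strand),
                   name = if (is.null(name)) sprintf("anchor_%d", seq_along(contig))
                          else as.character(name),
                   stringsAsFactors = FALSE)
  class(df) <- c("anchor_set", "data.frame")
  df
}

#' Read anchors from a BED file
#'
#' Each BED interval contributes one anchor point: the interval start for
#' plus-strand (or unstranded) entries, `end - 1` for minus-strand entries,
#' both in the package's 0-based convention. Strand is taken from BED
#' column 6 when present, defaulting to `+`.
#'
#' @param path path to a BED file (>= 3 columns).
#' @return an `anchor_set`.
#' @export
read_anchors <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && any(BiocGenerics::width(gr) < 1L)) {
    stop("BED interval with start >= end")
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "+"
  # GRanges is 1-based closed; BED start = start-1, BED end-1 = end-1
  pos0 <- ifelse(strand == "+",
                 BiocGenerics::start(gr) - 1L,
                 BiocGenerics::end(gr) - 1L)
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- NULL
  anchor_set(as.character(GenomicRanges::seqnames(gr)), pos0, strand, nm)
}
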