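#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] (multi-record,
#' line-wrapped and CRLF files, plain or gzip) that uppercases residues on
#' ingest. Soft-masked (lowercase) bases are treated as normal sequence; N and
#' other IUPAC ambiguity codes are preserved and excluded from pairing by the
#' detectors.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet], record order preserved.
#' @export
readFastaSequences <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path)
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                  error = function(e)
                      stop("malformed FASTA in '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    if (length(x) == 0L)
        stop("no sequence records in '", path, "'")
    seqs <- toupper(as.character(x))
    names(seqs) <- names(x)
    Biostrings::DNAStringSet(seqs)
}

#' Write inverted-repeat hits to a file
#'
#' Three output formats are supported. `"detectir"` writes one three-line
#' record per hit: header `>start|length|mismatchStem|gapCount`, the window
#' sequence, and the dot-bracket structure (coordinates are 1-based within the
#' hit's own sequence record). `"tsv"` writes the full hit table with a header
#' line. `"bed"` writes BED6 with 0-based half-open intervals, the name field
#' `length|mismatchStem|gapCount`, the mismatch total as score, and `+`
#' strand.
#'
#' @param x an [IRHits-class] object.
#' @param path output file path.
#' @param format `"detectir"`, `"tsv"` or `"bed"`.
#' @return invisibly, the path.
#' @export
writeIRHits <- function(x, path, format = c("detectir", "tsv", "bed")) {
    stopifnot(is(x, "IRHits"))
    format <- match.arg(format)
    df <- as.data.frame(x)
    if (format == "detectir") {
        writeLines(formatRecords(x), path)
    } else if (format == "tsv") {
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = TRUE)
    } else {
        bed <- data.frame(chrom = df$seqnames,
                          chromStart = df$start - 1L,
                          chromEnd = df$end,
                          name = sprintf("%d|%d|%d", df$irLength,
                                         df$mismatchStem, df$gapCount),
                          score = df$mismatchTotal,
                          strand = rep.int("+", nrow(df)))
        write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(path)
}

#' Parse a hit file written by [writeIRHits()]
#'
#' Recovers the hit table from any of the three output formats. The
#' `"detectir"` and `"bed"` formats do not carry every column: records parsed
#' from `"detectir"` have no sequence-record name (the header carries only
#' coordinates), and `"bed"` records carry neither window sequence nor
#' structure; missing columns are `NA`.
#'
#' @param path input file path.
#' @param format `"detectir"`, `"tsv"` or `"bed"`.
#' @return a data.frame with columns `seqnames`, `start`, `end`, `irLength`,
#'   `mismatchStem`, `gapCount`, `mismatchTotal`, `seq`, `structure`.
#' @export
parseIRHits <- function(path, format = c("detectir", "tsv", "bed")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("no such file: ", path)
    if (format == "tsv") {
        df <- read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(seqnames = "character",
                                        seq = "character",
                                        structure = "character"))
        return(df)
    }
    if (format == "bed") {
        bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
        if (ncol(bed) < 6L)
            stop("malformed BED: expected 6 columns")
        parts <- strsplit(bed[[4L]], "|", fixed = TRUE)
        if (any(lengths(parts) != 3L))
            stop("malformed BED name field: expected 'length|mismatch|gap'")
        parts <- matrix(as.integer(unlist(parts)), ncol = 3L, byrow = TRUE)
        return(data.frame(seqnames = as.character(bed[[1L]]),
                          start = bed[[2L]] + 1L, end = bed[[3L]],
                          irLength = parts[, 1L], mismatchStem = parts[, 2L],
                          gapCount = parts[, 3L],
                          mismatchTotal = parts[, 2L] + parts[, 3L],
                          seq = NA_character_, structure = NA_character_,
                          stringsAsFactors = FALSE))
    }
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(data.frame(seqnames = character(0), start = integer(0),
                          end = integer(0), irLength = integer(0),
                          mismatchStem = integer(0), gapCount = integer(0),
                          mismatchTotal = integer(0), seq = character(0),
                          structure = character(0)))
    if (length(lines) %% 3L != 0L)
        stop("malformed record file: line count not a multiple of 3")
    hdr <- lines[seq(1L, length(lines), by = 3L)]
    if (!all(startsWith(hdr, ">")))
        stop("malformed record file: header lines must start with '>'")
    parts <- strsplit(sub("^>", "", hdr), "|", fixed = TRUE)
    if (any(lengths(parts) != 4L))
        stop("malformed header: expected '>start|length|mismatch|gap'")
    parts <- matrix(as.integer(unlist(parts)), ncol = 4L, byrow = TRUE)
    data.frame(seqnames = NA_character_,
               start = parts[, 1L],
               end = parts[, 1L] + parts[, 2L] - 1L,
               irLength = parts[, 2L],
               mismatchStem = parts[, 3L],
               gapCount = parts[, 4L],
               mismatchTotal = parts[, 3L] + parts[, 4L],
               seq = lines[seq(2L, length(lines), by = 3L)],
               structure = lines[seq(3L, length(lines), by = 3L)],
               stringsAsFactors = FALSE)
}
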