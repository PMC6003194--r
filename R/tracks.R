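# Coverage-track normalization, bedGraph I/O and UCSC track-hub emission
# with the composite colour convention: total signal grey, reference
# haplotype blue, non-reference haplotype red.

#' Depth-normalize a coverage track
#'
#' Scales every value by `1e6 / library_size_fragments` (reads per
#' million). Allelic tracks must be normalized by the total
#' (allele-agnostic) library size so that hap1 + hap2 never exceeds the
#' total track after normalization. Re-normalizing an already normalized
#' track is an error.
#'
#' @param track A `coverage_track` (or `data.frame(chrom, start, end,
#'   value)`).
#' @param library_size_fragments Total aligned fragments of the library.
#' @return The normalized track, with attribute `normalization = "rpm"`.
#' @export
depth_normalize <- function(track, library_size_fragments) {
  if (library_size_fragments <= 0) stop("library size must be > 0")
  if (identical(attr(track, "normalization"), "rpm"))
    stop("track is already depth-normalized")
  track$value <- track$value * 1e6 / library_size_fragments
  attr(track, "normalization") <- "rpm"
  track
}

#' Write a coverage track as bedGraph
#'
#' Four-column, 0-based half-open bedGraph; values are printed at six
#' significant digits, so `read_bedgraph(write_bedgraph(t))` is lossless
#' at that precision.
#'
#' @param track `data.frame(chrom, start, end, value)`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end),
    score = signif(track$value, 6))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file as a coverage track
#'
#' @param path bedGraph path.
#' @return `data.frame(chrom, start, end, value)`, 0-based half-open,
#'   class `coverage_track` with `normalization = "raw"` (the file does
#'   not record normalization state).
#' @export
read_bedgraph <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    tr <- data.frame(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    tr <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     value = as.numeric(gr$score))
  }
  attr(tr, "normalization") <- "raw"
  class(tr) <- c("coverage_track", "data.frame")
  tr
}

TRACK_COLOURS <- c(total = "128,128,128", hap1 = "0,0,255", hap2 = "255,0,0")

#' Write a UCSC track hub for allelic composite tracks
#'
#' Emits `hub.txt`, `genomes.txt` and a `trackDb.txt` defining one
#' composite per dataset with three member tracks: total (allele-agnostic,
#' grey), reference haplotype (blue) and non-reference haplotype (red). A
#' structural self-check of the required keys runs before returning.
#'
#' @param datasets `data.frame(name, total, hap1, hap2)`: a dataset label
#'   and the three track file paths (relative to `out_dir` or absolute);
#'   zero rows yield a valid empty hub. Every referenced file must exist.
#' @param genome_label Assembly name written to `genomes.txt` (e.g.
#'   `"mm10"`).
#' @param out_dir Hub directory (created if absent).
#' @param hub_name Hub identifier.
#' @return `out_dir`, invisibly.
#' @export
write_trackhub <- function(datasets, genome_label, out_dir,
                           hub_name = "allelic_hub") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  datasets <- as.data.frame(datasets)
  for (i in seq_len(nrow(datasets)))
    for (col in c("total", "hap1", "hap2")) {
      f <- datasets[[col]][i]
      if (!file.exists(f) && !file.exists(file.path(out_dir, f)))
        stop("track file not found: ", f)
    }
  writeLines(c(
    paste("hub", hub_name),
    paste("shortLabel", hub_name),
    paste("longLabel", "Allele-specific composite coverage tracks"),
    "genomesFile genomes.txt",
    "email nobody@example.org"
  ), file.path(out_dir, "hub.txt"))
  writeLines(c(
    paste("genome", genome_label),
    "trackDb trackDb.txt"
  ), file.path(out_dir, "genomes.txt"))
  db <- character()
  for (i in seq_len(nrow(datasets))) {
    nm <- datasets$name[i]
    db <- c(db,
      paste("track", nm),
      "compositeTrack on",
      paste("shortLabel", nm),
      paste("longLabel", paste(nm, "total / reference / non-reference")),
      "type bedGraph",
      "visibility full",
      "")
    for (member in c("total", "hap1", "hap2")) {
      db <- c(db,
        paste0("\ttrack ", nm, "_", member),
        paste0("\tparent ", nm),
        paste0("\tshortLabel ", nm, " ", member),
        paste0("\tlongLabel ", nm, " ", member, " coverage"),
        paste0("\tbigDataUrl ", datasets[[member]][i]),
        "\ttype bedGraph",
        paste0("\tcolor ", TRACK_COLOURS[[member]]),
        "")
    }
  }
  writeLines(db, file.path(out_dir, "trackDb.txt"))
  check_trackhub(out_dir)
  invisible(out_dir)
}

#' Structural check of a track hub directory
#'
#' Verifies that `hub.txt` carries `hub`, `shortLabel`, `longLabel` and
#' `genomesFile` keys, `genomes.txt` carries `genome` and `trackDb`, and
#' every non-composite track stanza in `trackDb.txt` has `track`,
#' `bigDataUrl` and `type` keys.
#'
#' @param dir Hub directory.
#' @return `TRUE` invisibly; errors describe the first problem found.
#' @export
check_trackhub <- function(dir) {
  need_file <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing hub file: ", f)
    readLines(p)
  }
  keys_of <- function(lines) sub(" .*", "", trimws(lines[nzchar(trimws(lines))]))
  hub <- need_file("hub.txt")
  for (k in c("hub", "shortLabel", "longLabel", "genomesFile"))
    if (!k %in% keys_of(hub)) stop("hub.txt missing required key: ", k)
  gen <- need_file("genomes.txt")
  for (k in c("genome", "trackDb"))
    if (!k %in% keys_of(gen)) stop("genomes.txt missing required key: ", k)
  db <- need_file("trackDb.txt")
  # split into stanzas at blank lines
  grp <- cumsum(!nzchar(trimws(db)))
  for (g in unique(grp)) {
    stanza <- db[grp == g]
    keys <- keys_of(stanza)
    if (!length(keys)) next
    if (!"track" %in% keys) stop("trackDb.txt stanza without 'track' key")
    if (!"compositeTrack" %in% keys) {
      for (k in c("bigDataUrl", "type"))
        if (!k %in% keys)
          stop("trackDb.txt track '", stanza[1], "' missing key: ", k)
    }
  }
  invisible(TRUE)
}
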