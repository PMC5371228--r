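#' Read a bismark-style coverage file
#'
#' Expects the 6-column tab-separated coverage format: chrom, start, end,
#' methylation percentage, count methylated, count unmethylated. Counts are
#' authoritative; the percentage column is only validated (within 0.5
#' percentage points) and otherwise ignored. Records sharing a coordinate
#' (e.g. two sequencing runs of one sample) are collapsed by summing reads.
#'
#' @param path file path.
#' @param assume_one_based if `TRUE` (the bismark convention) positions are
#'   shifted to the package's 0-based convention on read.
#' @return data.frame with columns `chrom`, `pos` (0-based), `meth`,
#'   `unmeth`, `fraction` (`NA` when total reads are zero).
#' @export
read_coverage_file <- function(path, assume_one_based = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer(),
                      fraction = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6)) {
    stop("malformed coverage line ", which(nf != 6)[1], " in ", path,
         ": expected 6 tab-separated fields, got ", nf[nf != 6][1])
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 5]))
  unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad)) {
    stop("malformed coverage line ", bad[1], " in ", path,
         ": non-numeric coordinate or count")
  }
  if (any(meth < 0 | unmeth < 0)) {
    stop("negative counts at line ", which(meth < 0 | unmeth < 0)[1],
         " in ", path)
  }
  if (assume_one_based) pos <- pos - 1L
  if (any(pos < 0)) stop("negative position after coordinate shift in ", path)

  pct <- suppressWarnings(as.numeric(m[, 4]))
  tot <- meth + unmeth
  ok <- !is.na(pct) & tot > 0
  if (any(ok & abs(pct - 100 * meth / tot) > 0.5)) {
    warning("percentage column disagrees with counts by > 0.5 points in ",
            path, "; counts used")
  }

  chrom <- sub("^chr", "", m[, 1])
  key <- paste0(chrom, ":", pos)
  if (anyDuplicated(key)) {
    meth <- as.integer(rowsum(meth, key, reorder = FALSE))
    unmeth <- as.integer(rowsum(unmeth, key, reorder = FALSE))
    keep <- !duplicated(key)
    chrom <- chrom[keep]
    pos <- pos[keep]
  }
  tot <- meth + unmeth
  out <- data.frame(chrom = chrom, pos = pos, meth = meth, unmeth = unmeth,
                    fraction = ifelse(tot > 0, meth / tot, NA_real_),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write per-sample bismark-style coverage files
#'
#' One file `<sample_id>.cov` per sample under `dir`, 1-based coordinates,
#' omitting missing cells. Inverse of [read_coverage_file()] +
#' [assemble_matrix()] on counts.
#'
#' @param m a [meth_matrix()] carrying counts.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_coverage_files <- function(m, dir) {
  stopifnot(inherits(m, "meth_matrix"), !is.null(m$meth))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(m$sample_ids))
  for (i in seq_along(m$sample_ids)) {
    tot <- m$meth[i, ] + m$unmeth[i, ]
    keep <- which(tot > 0 & !is.na(m$fraction[i, ]))
    df <- data.frame(
      chrom = m$sites$chrom[keep],
      start = m$sites$pos[keep] + 1L,
      end = m$sites$pos[keep] + 1L,
      pct = round(100 * m$meth[i, keep] / tot[keep], 4),
      meth = m$meth[i, keep],
      unmeth = m$unmeth[i, keep]
    )
    paths[i] <- file.path(dir, paste0(m$sample_ids[i], ".cov"))
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Assemble per-sample coverage records into a methylation matrix
#'
#' Takes the union of sites across samples, ordered by (chrom, pos); cells
#' absent from a sample are missing. Metadata rows without data are dropped
#' with a warning; samples without metadata are an error.
#'
#' @param records named list of data.frames from [read_coverage_file()],
#'   names are sample ids.
#' @param meta sample metadata data.frame (see [check_sample_meta()]).
#' @return list with `matrix` (a [meth_matrix()]) and `meta` (row-matched).
#' @export
assemble_matrix <- function(records, meta) {
  if (!length(records)) stop("no coverage records supplied")
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids))) stop("records must be named by sample id")
  if (anyDuplicated(ids)) stop("duplicate sample id in records")

  all_sites <- unique(do.call(rbind, lapply(records, function(r)
    r[, c("chrom", "pos")])))
  ord <- order(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[ord, , drop = FALSE]
  key <- paste0(all_sites$chrom, ":", all_sites$pos)

  n <- length(records); p <- nrow(all_sites)
  meth <- matrix(0L, n, p)
  unmeth <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    r <- records[[i]]
    j <- match(paste0(r$chrom, ":", r$pos), key)
    meth[i, j] <- r$meth
    unmeth[i, j] <- r$unmeth
  }
  m <- meth_matrix(meth = meth, unmeth = unmeth,
                   sites = all_sites, sample_ids = ids)

  extra <- setdiff(meta$sample_id, ids)
  if (length(extra)) {
    warning("metadata rows without coverage data dropped: ",
            paste(extra, collapse = ", "))
    meta <- meta[!meta$sample_id %in% extra, , drop = FALSE]
  }
  meta <- check_sample_meta(meta, m)
  list(matrix = m, meta = meta)
}

#' Read/write the tab-separated sample metadata table
#' @param path file path
#' @return data.frame
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_sample_meta(meta)
}

#' @rdname read_sample_meta
#' @param meta metadata data.frame
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a fraction matrix as TSV (sites x samples, "NA" for missing)
#' @param m a [meth_matrix()]
#' @param path output path
#' @export
write_fraction_tsv <- function(m, path) {
  df <- data.frame(site_id = site_ids(m), t(m$fraction),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

region_vocab <- c("TSS/promoter", "5'UTR", "body", "exon", "intron",
                  "intergenic", "shelf", "island", "shore", "enhancer",
                  "bivalent", "H3K27me3", "H3K9ac", "H3K27ac", "H3K4me1",
                  "H3K4me3", "H3K36me3", "DNase")

read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 6) names(df)[4:6] <- c("name", "score", "strand")
  df$chrom <- sub("^chr", "", df$chrom)
  df
}

bed_to_granges <- function(bed) {
  # BED is half-open 0-based; GRanges is closed 1-based
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end),
    strand = if ("strand" %in% names(bed)) bed$strand else "*"
  )
}

sites_to_granges <- function(sites) {
  sites <- normalize_sites(sites)
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}

#' Annotate CpG sites with genomic region labels
#'
#' Intersects site coordinates with per-label interval sets (BED-style
#' half-open 0-based data.frames with columns `chrom`, `start`, `end` and
#' optionally `strand`, or file paths). Derived labels: `enhancer` is the
#' interval intersection of H3K27ac and H3K4me1; `bivalent` of H3K4me3 and
#' H3K27me3; a `TSS/promoter` track supplied as gene starts (BED6 with
#' strand) is expanded to the 2 kb strand-aware upstream window. Sites may
#' carry multiple labels; consumers apply their own precedence.
#'
#' @param sites sites data.frame (`chrom`, 0-based `pos`) or [meth_matrix()].
#' @param tracks named list of interval sets; names must come from the
#'   controlled vocabulary (histone marks, DNase, region classes,
#'   `TSS/promoter`).
#' @param promoter_upstream width in bases of the promoter window upstream
#'   of a transcription start (default 2000).
#' @return logical matrix sites x labels (input labels plus any derivable
#'   `enhancer`/`bivalent` columns).
#' @export
annotate_sites <- function(sites, tracks, promoter_upstream = 2000L) {
  if (inherits(sites, "meth_matrix")) sites <- sites$sites
  unknown <- setdiff(names(tracks), region_vocab)
  if (length(unknown)) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  }
  gr_sites <- sites_to_granges(sites)
  grs <- lapply(names(tracks), function(lab) {
    tr <- tracks[[lab]]
    if (is.character(tr)) tr <- read_bed(tr)
    gr <- bed_to_granges(tr)
    if (lab == "TSS/promoter") {
      # track gives transcription starts; promoter = 2 kb upstream,
      # strand-aware (upstream of a minus-strand start is numerically right)
      gr <- GenomicRanges::promoters(gr, upstream = promoter_upstream,
                                     downstream = 0L)
      gr <- GenomicRanges::trim(gr)
    }
    gr
  })
  names(grs) <- names(tracks)
  if (all(c("H3K27ac", "H3K4me1") %in% names(grs)) &&
      !"enhancer" %in% names(grs)) {
    grs$enhancer <- GenomicRanges::intersect(
      grs[["H3K27ac"]], grs[["H3K4me1"]], ignore.strand = TRUE)
  }
  if (all(c("H3K4me3", "H3K27me3") %in% names(grs)) &&
      !"bivalent" %in% names(grs)) {
    grs$bivalent <- GenomicRanges::intersect(
      grs[["H3K4me3"]], grs[["H3K27me3"]], ignore.strand = TRUE)
  }
  out <- vapply(grs, function(gr) {
    IRanges::overlapsAny(gr_sites, gr, ignore.strand = TRUE)
  }, logical(length(gr_sites)))
  out <- matrix(out, nrow = length(gr_sites),
                dimnames = list(site_ids(sites), names(grs)))
  out
}
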