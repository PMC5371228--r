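#' Map CpG sites into an orthologous array-probe space
#'
#' Joins mouse site coordinates to a precomputed coordinate-mapping table
#' (liftOver output consumed as a table, not computed here) and intersects
#' the lifted coordinates with an array-probe manifest. Mouse sites whose
#' lifted position matches a probe coordinate (within `slop` bases; nearest
#' probe wins ties) are included; several mouse sites may land on one probe,
#' recorded as a group for later averaging. Sites without a lift record or a
#' probe hit are excluded and reported via a message.
#'
#' @param sites sites data.frame / [meth_matrix()] of mouse CpGs.
#' @param mapping data.frame with columns `chrom_src`, `pos_src`,
#'   `chrom_dst`, `pos_dst` (0-based positions both sides).
#' @param manifest data.frame with columns `probe_id`, `chrom`, `pos`
#'   (0-based probe CpG coordinate).
#' @param slop maximum |lifted - probe| distance counted as intersection
#'   (default 0: exact coordinate equality).
#' @return data.frame (`mouse_site`, `probe_id`, `human_site`), one row per
#'   mapped mouse site; class `ortholog_map`.
#' @export
build_ortholog_space <- function(sites, mapping, manifest, slop = 0L) {
  if (inherits(sites, "meth_matrix")) sites <- sites$sites
  sites <- normalize_sites(sites)
  stopifnot(all(c("chrom_src", "pos_src", "chrom_dst", "pos_dst") %in%
                  names(mapping)),
            all(c("probe_id", "chrom", "pos") %in% names(manifest)))
  mapping$chrom_src <- sub("^chr", "", as.character(mapping$chrom_src))
  mapping$chrom_dst <- sub("^chr", "", as.character(mapping$chrom_dst))
  manifest$chrom <- sub("^chr", "", as.character(manifest$chrom))

  mk <- paste0(mapping$chrom_src, ":", mapping$pos_src)
  hit <- match(site_ids(sites), mk)
  n_unlifted <- sum(is.na(hit))
  if (n_unlifted) message(n_unlifted, " site(s) without a lift record excluded")

  lifted_chrom <- mapping$chrom_dst[hit]
  lifted_pos <- mapping$pos_dst[hit]

  probe <- rep(NA_integer_, nrow(sites))
  for (i in which(!is.na(hit))) {
    cand <- which(manifest$chrom == lifted_chrom[i] &
                    abs(manifest$pos - lifted_pos[i]) <= slop)
    if (length(cand)) {
      d <- abs(manifest$pos[cand] - lifted_pos[i])
      cand <- cand[order(d, manifest$probe_id[cand])]
      probe[i] <- cand[1]
    }
  }
  keep <- which(!is.na(probe))
  if (!length(keep)) stop("empty intersection with the probe manifest")
  n_noprobe <- sum(!is.na(hit)) - length(keep)
  if (n_noprobe) message(n_noprobe, " lifted site(s) without a probe hit excluded")

  out <- data.frame(
    mouse_site = site_ids(sites)[keep],
    probe_id = manifest$probe_id[probe[keep]],
    human_site = paste0(manifest$chrom[probe[keep]], ":",
                        manifest$pos[probe[keep]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Collapse a mouse matrix to probe space
#'
#' Per sample, a probe's value is the unweighted mean of the nonmissing
#' fractions of the mouse sites in its group; missing iff all group members
#' are missing. Counts are dropped (averaged fractions no longer correspond
#' to reads).
#'
#' @param m a [meth_matrix()] covering the map's mouse sites.
#' @param map an ortholog map data.frame (`mouse_site`, `probe_id`,
#'   `human_site`).
#' @return a [meth_matrix()] over probes, sites taken from the human
#'   coordinates; column names are probe ids.
#' @export
collapse_to_probes <- function(m, map) {
  idx <- match(map$mouse_site, site_ids(m))
  if (anyNA(idx)) {
    stop("matrix does not cover mapped mouse sites: ",
         paste(utils::head(map$mouse_site[is.na(idx)], 5), collapse = ", "))
  }
  probes <- unique(map$probe_id)
  fr <- matrix(NA_real_, nrow(m$fraction), length(probes))
  for (k in seq_along(probes)) {
    cols <- idx[map$probe_id == probes[k]]
    fr[, k] <- rowMeans(m$fraction[, cols, drop = FALSE], na.rm = TRUE)
  }
  fr[is.nan(fr)] <- NA_real_
  hs <- map$human_site[match(probes, map$probe_id)]
  parts <- strsplit(hs, ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1),
                      pos = as.integer(vapply(parts, `[`, "", 2)))
  out <- meth_matrix(fraction = fr, sites = sites, sample_ids = m$sample_ids)
  colnames(out$fraction) <- probes
  out
}

#' Region-wise enrichment of age-associated sites
#'
#' For each region label, builds the 2x2 table of (age-associated vs not) x
#' (in-region vs not, for that region alone, so each site is counted once
#' per test). Reports the sample odds ratio (a*d)/(b*c) and the two-sided
#' Fisher exact p-value; OR > 1 means over-representation. A table with a
#' zero margin has an undefined OR (`NA`) and p = 1.
#'
#' @param age_flags logical vector over the site universe.
#' @param annotation logical matrix sites x labels ([annotate_sites()]).
#' @param regions labels to test (default all annotation columns).
#' @return data.frame: region, a, b, c, d, odds_ratio, p_value.
#' @export
region_enrichment <- function(age_flags, annotation,
                              regions = colnames(annotation)) {
  stopifnot(length(age_flags) == nrow(annotation),
            all(regions %in% colnames(annotation)))
  res <- lapply(regions, function(r) {
    inr <- annotation[, r]
    a <- sum(age_flags & inr)
    b <- sum(age_flags & !inr)
    c_ <- sum(!age_flags & inr)
    d <- sum(!age_flags & !inr)
    tab <- matrix(c(a, c_, b, d), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      or <- NA_real_; p <- 1
    } else {
      or <- (a * d) / (b * c_)
      p <- stats::fisher.test(tab)$p.value
    }
    data.frame(region = r, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least `n_overlap` common sites
#' between two sets of sizes `n_set_a` and `n_set_b` drawn from a universe
#' of `n_universe` sites.
#'
#' @param n_universe,n_set_a,n_set_b,n_overlap nonnegative counts.
#' @return p-value, P(X >= n_overlap) with X ~ Hypergeom.
#' @export
overlap_test <- function(n_universe, n_set_a, n_set_b, n_overlap) {
  if (n_overlap > min(n_set_a, n_set_b) ||
      max(n_set_a, n_set_b) > n_universe ||
      n_overlap < 0 || n_overlap < n_set_a + n_set_b - n_universe) {
    stop("inconsistent overlap counts")
  }
  stats::phyper(n_overlap - 1, n_set_a, n_universe - n_set_a, n_set_b,
                lower.tail = FALSE)
}
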