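# SPEC-OCCU specificity/occupancy, specialist classification, core-OTU
# sets with occupancy thresholds, set-overlap (Venn) arithmetic, and
# phylum-composition summaries.

#' Specificity and occupancy per OTU and group
#'
#' Specificity of OTU `i` for group `g` is its share of group-mean relative
#' abundances: `spec(i, g) = mean relabund in g / sum over groups of mean
#' relabund`; with `method = "sum"` the share of summed abundances is used
#' instead. Occupancy is the presence fraction within the group. Spec sums
#' to 1 across groups for every OTU with nonzero total abundance.
#'
#' @param table relative-abundance (or count) matrix.
#' @param groups factor of group labels, one per sample (>= 2 groups).
#' @param method `"mean"` (group-mean shares, default) or `"sum"`.
#' @return data.frame `otu_id`, `group`, `spec`, `occ`, `mean_relabund`.
#' @export
spec_occ <- function(table, groups, method = c("mean", "sum")) {
  method <- match.arg(method)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups")
  if (all(rowSums(table) == 0)) stop("no OTU present anywhere")
  lev <- levels(droplevels(groups))
  agg <- sapply(lev, function(g) {
    sub <- table[, groups == g, drop = FALSE]
    if (method == "mean") rowMeans(sub) else rowSums(sub)
  })
  occ <- sapply(lev, function(g) rowMeans(table[, groups == g, drop = FALSE] > 0))
  tot <- rowSums(agg)
  spec <- sweep(agg, 1L, ifelse(tot > 0, tot, NA_real_), "/")
  mr <- sapply(lev, function(g) rowMeans(table[, groups == g, drop = FALSE]))
  out <- expand.grid(otu_id = rownames(table), group = lev,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$spec <- as.vector(spec)
  out$occ <- as.vector(occ)
  out$mean_relabund <- as.vector(mr)
  out
}

#' Classify specialists from SPEC-OCCU records
#'
#' Specialists satisfy `spec >= spec_min` and `occ >= occ_min`
#' (inclusive thresholds).
#'
#' @param records data.frame from [spec_occ()].
#' @param spec_min,occ_min inclusive thresholds (default 0.7).
#' @return `records` subset of specialists, with an `is_specialist` flag
#'   added to the full set in `attr(, "records")`.
#' @export
classify_specialists <- function(records, spec_min = 0.7, occ_min = 0.7) {
  records$is_specialist <- !is.na(records$spec) &
    records$spec >= spec_min & records$occ >= occ_min
  out <- records[records$is_specialist, , drop = FALSE]
  attr(out, "records") <- records
  out
}

#' Within-group core OTU sets with overlap report
#'
#' Core membership is within-group occupancy at or above `occ_min`. The
#' overlap report for every group pair gives shared and group-specific
#' counts and shares, satisfying `|A union B| = |A| + |B| - |A intersect B|`.
#'
#' @param table count or abundance matrix.
#' @param groups factor of group labels.
#' @param occ_min inclusive occupancy threshold (default 0.7).
#' @return list with `sets` (named list of OTU id vectors) and `overlap`
#'   (data.frame per group pair).
#' @export
core_sets <- function(table, groups, occ_min = 0.7) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs >= 2 samples")
  lev <- levels(droplevels(groups))
  sets <- setNames(lapply(lev, function(g) {
    occ <- rowMeans(table[, groups == g, drop = FALSE] > 0)
    rownames(table)[occ >= occ_min]
  }), lev)
  list(sets = sets, overlap = overlap_report(sets))
}

#' Per-group detected OTU sets with overlap report
#'
#' Detection is a positive count in at least one sample of the group.
#'
#' @param table count matrix.
#' @param groups factor of group labels.
#' @return list with `sets` and `overlap` as in [core_sets()].
#' @export
detected_sets <- function(table, groups) {
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  sets <- setNames(lapply(lev, function(g) {
    rownames(table)[rowSums(table[, groups == g, drop = FALSE] > 0) > 0]
  }), lev)
  list(sets = sets, overlap = overlap_report(sets))
}

#' Pairwise set-overlap (Venn) arithmetic
#'
#' @param sets named list of id vectors.
#' @return data.frame per unordered pair: sizes, shared, specifics, union,
#'   and shared shares of each set.
#' @export
overlap_report <- function(sets) {
  nm <- names(sets)
  if (length(nm) < 2L) return(data.frame())
  rows <- list()
  for (a in seq_along(nm)[-length(nm)]) {
    for (b in (a + 1L):length(nm)) {
      sa <- unique(sets[[a]]); sb <- unique(sets[[b]])
      shared <- length(intersect(sa, sb))
      rows[[length(rows) + 1L]] <- data.frame(
        set_a = nm[a], set_b = nm[b],
        size_a = length(sa), size_b = length(sb),
        shared = shared,
        a_specific = length(sa) - shared,
        b_specific = length(sb) - shared,
        union = length(union(sa, sb)),
        shared_of_a = if (length(sa)) shared / length(sa) else NA_real_,
        shared_of_b = if (length(sb)) shared / length(sb) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Phylum composition of an OTU set
#'
#' @param otu_set character vector of OTU ids.
#' @param taxonomy taxonomy data.frame with `otu_id` and `phylum`; ids not
#'   covered become `"unclassified"`.
#' @return data.frame `phylum`, `count`, `share` (shares sum to 1), sorted
#'   by decreasing share.
#' @export
phylum_composition <- function(otu_set, taxonomy) {
  if (length(otu_set) == 0L) stop("empty OTU set")
  phy <- taxonomy$phylum[match(otu_set, taxonomy$otu_id)]
  phy[is.na(phy) | phy == ""] <- "unclassified"
  tab <- sort(table(phy), decreasing = TRUE)
  data.frame(phylum = names(tab), count = as.integer(tab),
             share = as.numeric(tab) / length(otu_set),
             stringsAsFactors = FALSE, row.names = NULL)
}
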