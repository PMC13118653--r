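# Data model and file I/O: OTU count tables, trees, sample metadata,
# dam geometry, environmental and taxonomy tables.

validate_community_table <- function(x) {
  if (!is.matrix(x)) stop("community table must be a matrix")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("community table is empty")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("community table needs OTU row names and sample column names")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate OTU ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (any(!is.finite(x))) stop("non-numeric or missing counts")
  if (any(x < 0)) stop("negative counts")
  if (any(abs(x - round(x)) > 1e-8)) stop("non-integer counts")
  storage.mode(x) <- "double"
  x
}

#' Read an OTU count table
#'
#' Reads a tab- or comma-separated taxa-by-samples matrix (header row of
#' sample ids, first column of OTU ids). Orientation is taxa-as-rows by
#' default, the common amplicon convention; `orientation = "samples_rows"`
#' transposes, and `"auto"` keeps whichever axis is longer as taxa.
#'
#' @param path file path.
#' @param orientation one of `"taxa_rows"`, `"samples_rows"`, `"auto"`.
#' @return numeric matrix of counts, OTUs in rows, samples in columns.
#' @export
read_community_table <- function(path,
                                 orientation = c("taxa_rows", "samples_rows", "auto")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE, row.names = NULL,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed table: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  if (orientation == "samples_rows" ||
      (orientation == "auto" && nrow(m) < ncol(m))) {
    m <- t(m)
  }
  validate_community_table(m)
}

#' Write an OTU count table as TSV (taxa as rows)
#'
#' @param table count matrix.
#' @param path output path.
#' @param id_column header for the OTU id column.
#' @export
write_community_table <- function(table, path, id_column = "otu_id") {
  df <- data.frame(rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library sizes (per-sample totals) of a count table
#' @param table count matrix.
#' @return named numeric vector of column sums.
#' @export
library_sizes <- function(table) colSums(table)

#' Read a rooted phylogeny from a Newick file
#'
#' Node support values are parsed but ignored by downstream calculations.
#' Missing branch lengths are an error unless `default_length` is given;
#' negative branch lengths are always rejected.
#'
#' @param path Newick file.
#' @param default_length replacement for missing branch lengths (default:
#'   error on missing lengths).
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path, default_length = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unparseable Newick: ", path)
  validate_tree(tree, default_length)
}

validate_tree <- function(tree, default_length = NULL) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  if (is.null(tree$edge.length)) {
    if (is.null(default_length)) stop("tree has no branch lengths")
    tree$edge.length <- rep(default_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_length)) stop("tree has missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- default_length
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Prune a phylogeny to the OTUs of a community table
#'
#' Drops all leaves absent from the table; path lengths between retained
#' leaves are conserved (degree-2 nodes are collapsed with lengths summed).
#'
#' @param tree an [ape::phylo].
#' @param table count matrix whose row names are the OTUs to keep, or a
#'   character vector of OTU ids.
#' @return the pruned tree.
#' @export
prune_to_table <- function(tree, table) {
  keep <- if (is.character(table)) table else rownames(table)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("OTUs absent from tree: ", paste(head(missing, 5L), collapse = ", "))
  }
  ape::keep.tip(tree, keep)
}

#' Filter OTUs by singleton status and prevalence
#'
#' A singleton is an OTU whose total count across all samples is 1. The
#' prevalence of an OTU is the fraction of samples in which it occurs; OTUs
#' with prevalence strictly below `min_prevalence` are removed.
#'
#' @param table count matrix.
#' @param drop_singletons remove total-count-1 OTUs.
#' @param min_prevalence minimum occurrence fraction, in `[0, 1]`.
#' @return the filtered matrix, with the removed OTU ids in
#'   `attr(, "removed")`.
#' @export
filter_otus <- function(table, drop_singletons = TRUE, min_prevalence = 0) {
  tot <- rowSums(table)
  prev <- rowMeans(table > 0)
  drop <- (drop_singletons & tot == 1) | prev < min_prevalence
  if (all(drop)) stop("filtering removed every OTU")
  out <- table[!drop, , drop = FALSE]
  attr(out, "removed") <- rownames(table)[drop]
  out
}

#' Total-sum scaling (relative abundances)
#'
#' @param table count (or already relative) matrix; every column total must
#'   be positive.
#' @return matrix whose columns sum to 1.
#' @export
tss_normalize <- function(table) {
  tot <- colSums(table)
  if (any(tot <= 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(table)[tot <= 0], collapse = ", "))
  }
  sweep(table, 2L, tot, "/")
}

#' Rarefy a count table to even depth
#'
#' Random subsampling without replacement (hypergeometric), the convention
#' for depth standardization of amplicon tables; a multinomial
#' (with-replacement) variant is available for sensitivity analysis.
#'
#' @param table count matrix.
#' @param depth target per-sample total.
#' @param seed optional integer seed.
#' @param drop_undersampled drop samples below `depth` instead of erroring.
#' @param method `"hypergeometric"` (default) or `"multinomial"`.
#' @return rarefied count matrix, every column summing to `depth`.
#' @export
rarefy_table <- function(table, depth, seed = NULL,
                         drop_undersampled = FALSE,
                         method = c("hypergeometric", "multinomial")) {
  method <- match.arg(method)
  stopifnot(depth >= 1)
  tot <- colSums(table)
  if (any(tot < depth)) {
    if (!drop_undersampled) {
      stop("samples below depth ", depth, ": ",
           paste(colnames(table)[tot < depth], collapse = ", "))
    }
    table <- table[, tot >= depth, drop = FALSE]
    if (ncol(table) == 0L) stop("no samples at or above depth ", depth)
  }
  with_seed(seed, {
    out <- apply(table, 2L, function(x) {
      n <- sum(x)
      if (n == depth) return(x)
      if (method == "hypergeometric") {
        idx <- sample.int(n, depth)
        cum <- cumsum(x)
        tabulate(findInterval(idx, cum, left.open = TRUE) + 1L,
                 nbins = length(x))
      } else {
        as.vector(rmultinom(1L, depth, x / n))
      }
    })
    rownames(out) <- rownames(table)
    out
  })
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `season`, `reach`, `replicate` (TSV).
#'
#' @param path file path.
#' @return data.frame with those columns; `reach` keeps file order of first
#'   appearance as its factor level order.
#' @export
read_sample_frame <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_frame(df)
}

validate_sample_frame <- function(df) {
  need <- c("sample_id", "season", "reach", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df$reach <- factor(df$reach, levels = unique(df$reach))
  df
}

#' Read a dam geometry table
#'
#' TSV with columns `reach` (ordered along the river) and `dams_to_next`
#' (number of dams between this reach and the next; last value ignored/NA).
#'
#' @param path file path.
#' @return data.frame with columns `reach`, `dams_to_next`.
#' @export
read_dam_geometry <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("reach", "dams_to_next") %in% names(df))) {
    stop("dam geometry needs columns reach, dams_to_next")
  }
  df
}

#' Read an environmental table
#'
#' TSV keyed by `reach` and `season` with physicochemical columns (Tem, DO,
#' pH, EC, Chla, TN, TP, NH4, NO3, NO2, COD, ...).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_env_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("reach", "season") %in% names(df))) {
    stop("environmental table needs columns reach, season")
  }
  df
}

#' Append dissolved inorganic nitrogen (DIN)
#'
#' DIN is the sum of ammonium, nitrate and nitrite nitrogen:
#' `DIN = NH4 + NO3 + NO2`.
#'
#' @param env environmental data.frame with columns `NH4`, `NO3`, `NO2`.
#' @return `env` with a `DIN` column appended (replaced if present).
#' @export
compute_din <- function(env) {
  need <- c("NH4", "NO3", "NO2")
  miss <- setdiff(need, names(env))
  if (length(miss)) stop("missing DIN component(s): ", paste(miss, collapse = ", "))
  env$DIN <- env$NH4 + env$NO3 + env$NO2
  env
}

#' Read a taxonomy table
#'
#' TSV with column `otu_id` and a `taxonomy` column holding a
#' semicolon-separated lineage (rank prefixes like `p__` optional), or
#' explicit rank columns. Unparsed ranks become `"unclassified"`.
#'
#' @param path file path.
#' @return data.frame with columns `otu_id`, `phylum` ... `genus`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"otu_id" %in% names(df)) stop("taxonomy needs an otu_id column")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  if ("taxonomy" %in% names(df)) {
    parts <- strsplit(df$taxonomy, ";", fixed = TRUE)
    parsed <- t(vapply(parts, function(p) {
      p <- sub("^\\s*[a-z]__", "", trimws(p))
      p[p == ""] <- "unclassified"
      out <- rep("unclassified", 7L)
      out[seq_len(min(7L, length(p)))] <- p[seq_len(min(7L, length(p)))]
      out
    }, character(7L)))
    colnames(parsed) <- ranks
    df <- cbind(df["otu_id"], as.data.frame(parsed, stringsAsFactors = FALSE))
  } else {
    for (r in intersect(ranks, names(df))) {
      df[[r]][is.na(df[[r]]) | df[[r]] == ""] <- "unclassified"
    }
  }
  df
}
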