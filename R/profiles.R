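#' Read an SOC aggregation map
#'
#' Two-column (plus label) lookup collapsing 6-digit SOC codes into
#' aggregated occupational groups for profile clustering. The packaged
#' default map covers the codes emitted by the synthetic cohort generator;
#' real studies supply their own.
#'
#' @param path CSV with columns `soc_code`, `agg_code`, `agg_label`.
#' @return data.frame.
#' @export
read_aggregation_map <- function(path = system.file("extdata",
                                                    "soc_aggregation.csv",
                                                    package = "occupex")) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_cols(m, c("soc_code", "agg_code", "agg_label"), "aggregation map")
  m
}

#' Mean exposure profile per aggregated SOC group
#'
#' Rows are aggregated SOC groups, columns the nine exposure types, entries
#' the mean score over the group's contributors. The `plain` variant
#' averages job-level scores over the jobs assigned to the group; the
#' `duration_adjusted` variant averages participant-level
#' duration-adjusted scores over the participants who worked in the group.
#' Groups with no scored contributors are dropped.
#'
#' @param scores An `occx_scores` object.
#' @param assignments An `occx_soc` table.
#' @param aggregation_map data.frame from [read_aggregation_map()]; codes
#'   absent from the map fall back to their 2-digit major group.
#' @param variant `"plain"` or `"duration_adjusted"`.
#' @return Numeric matrix with attribute `"n"` (contributors per row).
#' @export
build_profile_matrix <- function(scores, assignments, aggregation_map,
                                 variant = c("plain", "duration_adjusted")) {
  variant <- match.arg(variant)
  if (is.null(aggregation_map) || !nrow(aggregation_map))
    stop("aggregation map is empty")
  code <- assignments$final_code
  ai <- match(code, aggregation_map$soc_code)
  grp <- ifelse(is.na(ai), soc_major_group(code),
                aggregation_map$agg_label[ai])
  names(grp) <- assignments$job_id

  if (variant == "plain") {
    df <- scores$job_scores
    df$grp <- grp[df$job_id]
  } else {
    js <- scores$job_scores
    pg <- unique(data.frame(participant_id = js$participant_id,
                            grp = grp[js$job_id], stringsAsFactors = FALSE))
    df <- merge(scores$participant_duration_adjusted, pg,
                by = "participant_id")
  }
  df <- df[!is.na(df$score) & !is.na(df$grp), , drop = FALSE]
  if (!nrow(df)) stop("no scored contributors in any group")
  groups <- sort(unique(df$grp))
  types <- names(exposure_types())
  types <- types[types %in% df$type]
  key <- paste(df$grp, df$type, sep = "\r")
  sums <- rowsum(df$score, key)
  cnts <- rowsum(rep(1L, nrow(df)), key)
  m <- matrix(NA_real_, length(groups), length(types),
              dimnames = list(groups, types))
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  m[cbind(match(vapply(parts, `[`, "", 1L), groups),
          match(vapply(parts, `[`, "", 2L), types))] <-
    as.numeric(sums) / as.numeric(cnts)
  n_row <- rowsum(rep(1L, nrow(df)), df$grp)[groups, 1L]
  attr(m, "n") <- n_row
  m
}

#' Cluster exposure profiles
#'
#' Agglomerative hierarchical clustering of the group exposure profiles
#' using Euclidean distance; linkage is complete by default, configurable
#' to average or single. Profiles with any missing entry are dropped first.
#'
#' @param profile_matrix Matrix from [build_profile_matrix()].
#' @param method Linkage: `"complete"` (default), `"average"`, `"single"`.
#' @return An `hclust` tree (leaf labels = group names), or for a single
#'   remaining row a degenerate single-leaf tree of class
#'   `"occx_single_leaf"`.
#' @export
cluster_profiles <- function(profile_matrix,
                             method = c("complete", "average", "single")) {
  method <- match.arg(method)
  m <- profile_matrix[stats::complete.cases(profile_matrix), , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete profiles to cluster")
  if (nrow(m) == 1L)
    return(structure(list(labels = rownames(m)),
                     class = "occx_single_leaf"))
  stats::hclust(stats::dist(m, method = "euclidean"), method = method)
}

#' Export a dendrogram as Newick
#'
#' Writes the clustering tree in Newick format with branch lengths equal
#' to merge-height differences.
#'
#' @param tree An `hclust` from [cluster_profiles()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  if (inherits(tree, "occx_single_leaf")) {
    writeLines(paste0("(", tree$labels, ");"), path)
    return(invisible(path))
  }
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Metals score summary by SOC major group
#'
#' Per 2-digit major group: number of jobs, mean, SD, min, quartiles and
#' max of the job-level metals exposure score, sorted by mean descending.
#'
#' @param scores An `occx_scores` object.
#' @param assignments An `occx_soc` table.
#' @param type Exposure type to summarise (default `"metals"`).
#' @return data.frame: `major_group`, `n`, `mean`, `sd`, `min`, `q25`,
#'   `q50`, `q75`, `max`.
#' @export
metals_by_soc <- function(scores, assignments, type = "metals") {
  js <- scores$job_scores[scores$job_scores$type == type, , drop = FALSE]
  js$grp <- assignments$major_group[match(js$job_id, assignments$job_id)]
  js <- js[!is.na(js$score) & !is.na(js$grp), , drop = FALSE]
  out <- list()
  for (g in sort(unique(js$grp))) {
    x <- js$score[js$grp == g]
    out[[length(out) + 1L]] <- data.frame(
      major_group = g, n = length(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      min = min(x), q25 = score_quantile(x, 0.25),
      q50 = score_quantile(x, 0.5), q75 = score_quantile(x, 0.75),
      max = max(x), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out[order(-out$mean), , drop = FALSE]
}
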