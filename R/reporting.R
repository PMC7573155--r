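# Aggregation, reporting and pipeline orchestration --------------------------

#' Aggregate edge weights by functional network
#'
#' Sums the edge weights within and between node-label groups (e.g. the
#' seven cortical networks plus basal ganglia and cerebellum used to group
#' the study's 264 nodes). Labels are user-supplied; unlabeled nodes fall
#' into `"unassigned"`.
#'
#' @param weight_matrix Symmetric node-by-node matrix.
#' @param node_labels Data frame with columns `node` (integer id) and
#'   `network` (label), or a character vector of per-node labels.
#' @return Symmetric network-by-network matrix of summed weights.
#' @export
group_weights_by_network <- function(weight_matrix, node_labels) {
  W <- as.matrix(weight_matrix)
  n <- nrow(W)
  if (is.data.frame(node_labels)) {
    if (anyDuplicated(node_labels$node)) abort("duplicate node ids.")
    lab <- rep("unassigned", n)
    keep <- node_labels$node >= 1 & node_labels$node <= n
    lab[node_labels$node[keep]] <- as.character(node_labels$network[keep])
  } else {
    lab <- as.character(node_labels)
    if (length(lab) != n) abort("need one label per node.")
    lab[is.na(lab)] <- "unassigned"
  }
  groups <- sort(unique(lab))
  out <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  pairs <- edge_pairs(n)
  w <- ut_vec(W)
  gi <- lab[pairs[, 1]]
  gj <- lab[pairs[, 2]]
  for (e in seq_along(w)) {
    a <- gi[e]; b <- gj[e]
    out[a, b] <- out[a, b] + w[e]
    if (a != b) out[b, a] <- out[b, a] + w[e]
  }
  out
}

#' Run the full synthetic-study pipeline
#'
#' Chains every stage on generated data: questionnaire simulation, factor
#' model fit and projection scoring, connectivity study generation keyed to
#' the sum-score change, NBS pre-selection, and cross-validated prediction
#' (honest strategies plus the circular comparison), returning all
#' intermediate objects and a summary tibble in the layout of the study's
#' generalizability table (strategy x scheme).
#'
#' @param spec A [synth_spec()].
#' @param n_perm NBS permutations.
#' @param n_redraws 3-fold CV redraws.
#' @param direction NBS/selection contrast direction.
#' @param alpha NBS component significance level.
#' @param with_covariates Fit full models (sex, age, mean connectivity)?
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `fc_pipeline`: `items`, `factor_model`, `scores`
#'   (pre/post/change), `study`, `nbs`, `cv` (named list of `cv_result`s),
#'   and `summary` tibble.
#' @export
run_pipeline <- function(spec, n_perm = 1000, n_redraws = 200, direction = 1,
                         alpha = 0.10, with_covariates = TRUE,
                         seed = spec$seed) {
  items <- gen_questionnaire(spec, seed = seed)
  fm <- fit_factor_model(items$pre)
  pre_scores <- score_subjects(fm, items$pre)
  post_scores <- score_subjects(fm, items$post)
  change <- post_scores$sum_score - pre_scores$sum_score
  study <- gen_connectivity_study(spec, change, seed = seed + 1L,
                                  keep_matrices = FALSE)
  design <- edge_design(study$score_change,
                        study_covariates(study, with_covariates))
  nbs <- nbs_test(study$dz, design, direction = direction, alpha = alpha,
                  n_perm = n_perm, n_nodes = study$n_nodes, seed = seed + 2L)
  cv <- list(
    loocv_all = loocv(study, "all", with_covariates = with_covariates),
    loocv_threshold = loocv(study, "threshold", direction = direction,
                            with_covariates = with_covariates),
    cv3_all = repeated_3fold(study, "all", n_redraws = n_redraws,
                             with_covariates = with_covariates,
                             seed = seed + 3L),
    cv3_threshold = repeated_3fold(study, "threshold", direction = direction,
                                   n_redraws = n_redraws,
                                   with_covariates = with_covariates,
                                   seed = seed + 4L)
  )
  if (length(significant_component_edges(nbs))) {
    cv$loocv_nbs_circular <- insample_circular(study, nbs, "loocv",
                                               with_covariates = with_covariates)
    cv$cv3_nbs_circular <- insample_circular(study, nbs, "repeated3fold",
                                             n_redraws = n_redraws,
                                             with_covariates = with_covariates,
                                             seed = seed + 5L)
  }
  summary <- purrr::map_dfr(names(cv), function(nm) {
    x <- cv[[nm]]
    tibble::tibble(model = nm, scheme = x$scheme, strategy = x$strategy,
                   circular = x$circular, r = x$r_median,
                   n_flagged = x$n_flagged)
  })
  structure(list(items = items, factor_model = fm,
                 scores = list(pre = pre_scores, post = post_scores,
                               change = change),
                 study = study, nbs = nbs, cv = cv, summary = summary,
                 seed = seed),
            class = "fc_pipeline")
}

#' @export
print.fc_pipeline <- function(x, ...) {
  cat("<fc_pipeline> seed", x$seed, "\n")
  print(x$summary)
  invisible(x)
}

#' Write a generalizability report as Markdown
#'
#' @param pipeline A [run_pipeline()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report <- function(pipeline, path) {
  s <- pipeline$summary
  lines <- c(
    "# Generalizability report",
    "",
    sprintf("Factor model: %d factors on %d/%d items; KMO = %.3f; variance explained = %.2f%%",
            pipeline$factor_model$n_factors,
            length(pipeline$factor_model$retained_items),
            length(pipeline$factor_model$all_items),
            pipeline$factor_model$kmo,
            100 * pipeline$factor_model$variance_explained),
    sprintf("NBS: %d component(s) at edge threshold t = %.3f",
            length(pipeline$nbs$components), pipeline$nbs$t_thresh),
    "",
    "| model | scheme | strategy | circular | r | flagged |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %.3f | %d |",
            s$model, s$scheme, s$strategy, s$circular, s$r, s$n_flagged)
  )
  writeLines(lines, path)
  invisible(path)
}

# Delimited-text I/O ---------------------------------------------------------

#' Read/write an item table as delimited text
#'
#' Item tables are stored with a header row: a `subject` column plus one
#' column per item.
#'
#' @param path File path.
#' @param x Item table (tibble).
#' @param sep Field separator.
#' @return `read_item_table()` returns a tibble.
#' @export
read_item_table <- function(path, sep = "\t") {
  tibble::as_tibble(utils::read.delim(path, sep = sep,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' @rdname read_item_table
#' @export
write_item_table <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a square connectivity matrix as whitespace-delimited text
#'
#' @param path File path.
#' @param m Symmetric matrix.
#' @return `read_matrix()` returns a matrix.
#' @export
read_matrix <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  utils::write.table(m, path, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read a 4-D volume as NIfTI-1
#'
#' Thin wrappers over the RNifti package for interchange with imaging
#' tools; the in-memory representation everywhere else is a plain 4-D
#' array with a `spacing` attribute.
#'
#' @param volume 4-D array (isotropic 2 mm grid by default).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm.
#' @return `read_nifti_volume()` returns a 4-D array with the `spacing`
#'   attribute set from the header.
#' @export
write_nifti_volume <- function(volume, path, spacing = attr(volume, "spacing") %||% 2) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("writing NIfTI requires the RNifti package.")
  }
  img <- RNifti::asNifti(unclass(volume))
  RNifti::pixdim(img) <- c(rep(spacing, 3), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("reading NIfTI requires the RNifti package.")
  }
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)[1]
  out
}

#' Serialize a factor model to JSON
#'
#' Stores loadings, score weights, pre-sample means/SDs (sample SD, n-1),
#' KMO/MSA and the item-removal audit trail, sufficient to re-score new
#' item tables with [score_subjects()].
#'
#' @param model A `factor_model`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_factor_model <- function(model, path) {
  payload <- list(
    all_items = model$all_items, retained_items = model$retained_items,
    dropped_items = model$dropped_items, n_factors = model$n_factors,
    loadings = model$loadings, rotation = model$rotation,
    score_weights = model$score_weights,
    communalities = model$communalities, kmo = model$kmo, msa = model$msa,
    variance_explained = model$variance_explained,
    item_means = model$item_means, item_sds = model$item_sds,
    sd_denominator = "n-1")
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_factor_model
#' @export
read_factor_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("loadings", "rotation", "score_weights")) x[[f]] <- as.matrix(x[[f]])
  rownames(x$loadings) <- rownames(x$score_weights) <- x$retained_items
  colnames(x$loadings) <- colnames(x$score_weights) <-
    paste0("F", seq_len(x$n_factors))
  names(x$item_means) <- names(x$item_sds) <- x$retained_items
  x$dropped_items <- tibble::as_tibble(x$dropped_items)
  class(x) <- "factor_model"
  x
}
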