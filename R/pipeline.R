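#' Build a run configuration
#'
#' Collects the run-level parameters of the end-to-end analysis. The
#' importance level is always `p = 1/L` and never set independently, and
#' the same subsample size applies to both conditions.
#'
#' @param expr1,expr2 Paths to the two condition expression tables.
#' @param out_dir Output directory (created if absent).
#' @param keep_list Optional path to a one-id-per-line gene keep-list
#'   (e.g. protein-coding ids).
#' @param dialect1,dialect2 Table dialects, `"tsv"` or `"gct"`.
#' @param condition1,condition2 Condition labels.
#' @param subsample_size Subsample size n, or `NULL` for
#'   [default_subsample_size()] per condition sample count (the smaller of
#'   the two conditions' defaults, so both use the same n).
#' @param L Threshold draw size (default 1e5; importance level p = 1/L).
#' @param m Threshold draw count (default 100).
#' @param seed RNG seed for the threshold draws (default 1).
#' @param sigma_fallback Sigma used for a condition without subsampling
#'   (default 0).
#' @return A list of class `csd_config`.
#' @export
csd_config <- function(expr1, expr2, out_dir,
                       keep_list = NULL,
                       dialect1 = "tsv", dialect2 = "tsv",
                       condition1 = "condition1", condition2 = "condition2",
                       subsample_size = NULL, L = 1e5, m = 100,
                       seed = 1, sigma_fallback = 0) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  structure(list(expr1 = expr1, expr2 = expr2, out_dir = out_dir,
                 keep_list = keep_list,
                 dialect1 = dialect1, dialect2 = dialect2,
                 condition1 = condition1, condition2 = condition2,
                 subsample_size = subsample_size, L = L, m = m,
                 seed = seed, sigma_fallback = sigma_fallback),
            class = "csd_config")
}

#' Read a run configuration from a YAML file
#'
#' Accepts the keys of [csd_config()].
#'
#' @param path Path to a YAML file.
#' @return A `csd_config`.
#' @export
read_csd_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(csd_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(csd_config, cfg)
}

write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full CSD pipeline
#'
#' Executes read -> filter -> align -> subsample design -> correlation
#' profiles with standard errors per condition -> C/S/D scores ->
#' sampled-maxima thresholds -> classification -> network assembly -> node
#' summaries -> components and hubs, writing every intermediate and final
#' table to `out_dir` along with a JSON manifest of parameters, seeds and
#' per-stage counts. Any stage failure aborts with the stage name and
#' leaves a `FAILED` marker file next to the partial outputs. Numeric TSV
#' output is written at 6 significant digits so reruns diff cleanly.
#'
#' @param cfg A [csd_config()] (or path to a YAML config).
#' @return Invisibly, the manifest list.
#' @export
run_csd_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_csd_config(cfg)
  if (!inherits(cfg, "csd_config")) stop("cfg must be a csd_config", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("csdnet")),
                   parameters = unclass(cfg), stages = list(), outputs = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  m1 <- stage("read", read_expression_table(cfg$expr1, cfg$dialect1, cfg$condition1))
  m2 <- stage("read", read_expression_table(cfg$expr2, cfg$dialect2, cfg$condition2))
  if (!is.null(cfg$keep_list)) {
    keep <- readLines(cfg$keep_list)
    keep <- keep[nzchar(keep)]
    m1 <- stage("filter", filter_genes(m1, keep))
    m2 <- stage("filter", filter_genes(m2, keep))
  }
  al <- stage("align", align_matrices(m1, m2))
  m1 <- al$m1; m2 <- al$m2
  manifest$stages$genes_aligned <- nrow(m1)
  manifest$stages$samples <- c(ncol(m1), ncol(m2))

  n <- cfg$subsample_size
  if (is.null(n)) {
    n <- min(default_subsample_size(ncol(m1)), default_subsample_size(ncol(m2)),
             na.rm = FALSE)
  }
  profiles <- stage("correlate", {
    if (is.na(n) || n > min(ncol(m1), ncol(m2))) {
      message("subsampling not possible for at least one condition; ",
              "using sigma_fallback = ", cfg$sigma_fallback)
      list(pc1 = pair_correlation_profile(m1, NULL, cfg$sigma_fallback),
           pc2 = pair_correlation_profile(m2, NULL, cfg$sigma_fallback))
    } else {
      d1 <- generate_subsample_design(ncol(m1), n)
      d2 <- generate_subsample_design(ncol(m2), n)
      list(pc1 = pair_correlation_profile(m1, d1, cfg$sigma_fallback),
           pc2 = pair_correlation_profile(m2, d2, cfg$sigma_fallback))
    }
  })
  manifest$stages$subsample_size <- if (profiles$pc1$subsampling_used) n else NA
  manifest$stages$n_subsamples <- c(profiles$pc1$n_subsamples,
                                    profiles$pc2$n_subsamples)

  st <- stage("score", csd_score_table(profiles$pc1, profiles$pc2))
  manifest$stages$pairs_scored <- nrow(st)
  manifest$stages$pairs_dropped_undefined <- attr(st, "n_dropped_undefined")
  manifest$outputs$scores <- write_tsv(st, file.path(cfg$out_dir, "scores.tsv"))

  L <- min(cfg$L, nrow(st))
  if (L < cfg$L) {
    message("L reduced to the number of scored pairs (", L, ")")
  }
  th <- stage("threshold", determine_thresholds(st, L = L, m = cfg$m,
                                                seed = cfg$seed))
  th_path <- file.path(cfg$out_dir, "thresholds.yaml")
  yaml::write_yaml(list(X_C = th$X_C, X_S = th$X_S, X_D = th$X_D,
                        p = th$p, L = th$L, m = th$m, seed = cfg$seed), th_path)
  manifest$outputs$thresholds <- th_path

  typed <- stage("classify", classify_pairs(st, th))
  manifest$stages$links <- as.list(table(factor(typed$type,
                                                levels = c("C", "S", "D"))))
  if (nrow(typed) == 0L) {
    message("no pair exceeded any cutoff; empty network")
    manifest$outputs$edges <- write_tsv(
      data.frame(gene_a = character(), gene_b = character(),
                 type = character(), score = numeric(),
                 rho1 = numeric(), rho2 = numeric()),
      file.path(cfg$out_dir, "network_edges.tsv"))
  } else {
    net <- stage("network", assemble_network(typed))
    paths <- write_network_files(net, file.path(cfg$out_dir, "network"))
    manifest$outputs$edges <- unname(paths[["edges"]])
    manifest$outputs$nodes <- unname(paths[["nodes"]])
    comp <- component_decomposition(net)
    manifest$outputs$components <- write_tsv(comp,
                                             file.path(cfg$out_dir, "components.tsv"))
    hubs <- hub_report(net, top_n = 5)
    manifest$outputs$hubs <- write_tsv(
      do.call(rbind, Map(cbind, table = names(hubs), hubs)),
      file.path(cfg$out_dir, "hubs.tsv"))
    manifest$stages$nodes <- igraph::vcount(net)
    manifest$stages$edges <- igraph::ecount(net)
  }
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  manifest$outputs$manifest <- manifest_path
  invisible(manifest)
}
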