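# End-to-end pipeline: curation -> gap/interaction discovery -> community
# simulation -> AMG augmentation -> objective suite, with plain-text
# artifacts, a manifest with input hashes, and stage caching.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Validate and normalise a pipeline configuration
#'
#' @param config list or YAML path with fields: `bundle_dir` (a directory
#'   written by [write_bundle()]), `out_dir`, and optionally `method`
#'   (`"kkt"`/`"joint"`, default `"kkt"`), `stages` (character subset of
#'   curate, gaps, community, amg, objectives), `seed`.
#' @return validated config list; referenced paths are checked before any
#'   solver is invoked.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$bundle_dir) || is.null(config$out_dir)) {
    stop_fluxcom("pipeline config needs bundle_dir and out_dir")
  }
  config$method <- config$method %||% "kkt"
  config$stages <- config$stages %||%
    c("curate", "gaps", "community", "amg", "objectives")
  need <- c("db_universal.tsv", "transporter_kb.tsv", "taxonomy.yaml",
            "diet.yaml", "shared.yaml")
  for (f in file.path(config$bundle_dir, need)) {
    if (!file.exists(f)) stop_fluxcom("pipeline input missing: ", f)
  }
  if (length(list.files(file.path(config$bundle_dir, "models"))) == 0) {
    stop_fluxcom("pipeline input missing: ",
                 file.path(config$bundle_dir, "models"))
  }
  config
}

input_hashes <- function(bundle_dir) {
  files <- sort(list.files(bundle_dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", bundle_dir, "/?"), "", names(h))
  h
}

#' Run the full pipeline
#'
#' Stages run in order (curate, gaps, community, amg, objectives), each
#' writing TSV/JSON artifacts under `out_dir` and recording itself in
#' `manifest.json` together with a hash of every input file. A rerun with
#' unchanged inputs skips stages whose artifacts already exist (hash
#' match). Failures abort immediately, naming the stage.
#'
#' @param config see [pipeline_config()].
#' @return invisible list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hashes <- input_hashes(config$bundle_dir)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  } else list(stages = list())
  bundle <- read_bundle(config$bundle_dir)
  method <- config$method
  results <- list()

  cached <- function(stage) {
    st <- manifest$stages[[stage]]
    !is.null(st) && identical(unlist(st$inputs), as.vector(hashes)) &&
      all(file.exists(file.path(out, unlist(st$outputs))))
  }
  record <- function(stage, outputs) {
    manifest$stages[[stage]] <<- list(status = "complete",
                                      inputs = as.vector(hashes),
                                      outputs = outputs,
                                      time = format(Sys.time(),
                                                    "%Y-%m-%dT%H:%M:%S"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               manifest_path)
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    if (cached(stage)) {
      results[[stage]] <<- "cached"
      return(invisible(NULL))
    }
    outputs <- tryCatch(fn(), error = function(e) {
      stop_fluxcom("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e))
    })
    record(stage, outputs)
  }

  run_stage("curate", function() {
    outs <- character(0)
    for (m in bundle$members) {
      bal <- check_balance(m)
      outs <- c(outs, basename(write_tsv(bal$table,
        file.path(out, paste0("curate_balance_", m$id, ".tsv")))))
      ub <- find_unbounded(m)
      lr <- group_loops(m, ub)
      loops_doc <- list(unbounded = ub$unbounded,
                        groups = lapply(lr$groups, function(g)
                          list(reactions = g$reactions,
                               coefficients = as.list(g$coefficients))))
      f <- file.path(out, paste0("curate_loops_", m$id, ".json"))
      writeLines(jsonlite::toJSON(loops_doc, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), f)
      outs <- c(outs, basename(f))
      outs <- c(outs, basename(write_tsv(
        data.frame(reaction = find_blocked(m)),
        file.path(out, paste0("curate_blocked_", m$id, ".tsv")))))
      outs <- c(outs, basename(write_tsv(find_duplicates(m),
        file.path(out, paste0("curate_duplicates_", m$id, ".tsv")))))
    }
    outs
  })

  pre_cm <- build_community(bundle$members, bundle$shared, bundle$diet)
  run_stage("gaps", function() {
    tab <- discover_interactions(pre_cm, bundle$kb, bundle$tax,
                                 bundle$db_universal, phase = "pre_AMG")
    results$interactions_pre <<- tab
    basename(write_tsv(tab, file.path(out, "interactions_pre.tsv")))
  })
  if (is.null(results$interactions_pre) && "gaps" %in% config$stages) {
    results$interactions_pre <-
      utils::read.delim(file.path(out, "interactions_pre.tsv"))
  }

  # members with discovered de novo transporters incorporated
  filled_members <- bundle$members
  if (!is.null(results$interactions_pre) &&
      nrow(results$interactions_pre) > 0) {
    dn <- results$interactions_pre
    dn <- dn[dn$status == "de_novo_interaction" &
               !is.na(dn$transport_reaction), , drop = FALSE]
    for (i in seq_len(nrow(dn))) {
      src_db <- if (identical(dn$source[[i]], "universal"))
        bundle$db_universal else member_as_db(bundle$members[[dn$source[[i]]]])
      entry <- src_db$entries[[dn$transport_reaction[[i]]]]
      if (is.null(entry)) next
      recv <- filled_members[[dn$receiver[[i]]]]
      keys <- vapply(recv$reactions, function(r) stoich_key(r$stoichiometry), "")
      if (!stoich_key(entry$stoichiometry) %in% keys) {
        filled_members[[dn$receiver[[i]]]] <-
          validate_model(add_reactions(recv, list(entry)))
      }
    }
  }
  cm <- build_community(filled_members, bundle$shared, bundle$diet)

  run_stage("community", function() {
    sol <- solve_optcom(cm, community_objective("growth"), method = method)
    results$solution <<- sol
    outs <- c(
      basename(write_tsv(data.frame(member = names(sol$member_biomass),
                                    biomass = as.numeric(sol$member_biomass)),
                         file.path(out, "community_biomass.tsv"))),
      basename(write_tsv(sol$pool, file.path(out, "community_pool.tsv"))),
      basename(write_tsv(sol$transactions,
                         file.path(out, "community_transactions.tsv"))))
    outs
  })

  post_members <- filled_members
  if ("amg" %in% config$stages) {
    for (k in names(bundle$amg)) {
      post_members[[k]] <- apply_amg(post_members[[k]], bundle$amg[[k]])
    }
  }
  run_stage("amg", function() {
    post_cm <- build_community(post_members, bundle$shared, bundle$diet)
    tab_post <- discover_interactions(post_cm, bundle$kb, bundle$tax,
                                      bundle$db_universal, phase = "post_AMG")
    results$interactions_post <<- tab_post
    dif <- diff_interactions(results$interactions_pre, tab_post)
    outs <- c(
      basename(write_tsv(tab_post, file.path(out, "interactions_post.tsv"))),
      basename(write_tsv(dif$lost, file.path(out, "interactions_lost.tsv"))),
      basename(write_tsv(dif$retained,
                         file.path(out, "interactions_retained.tsv"))))
    outs
  })

  run_stage("objectives", function() {
    post_cm <- build_community(post_members, bundle$shared, bundle$diet)
    specs <- bundle$objectives %||%
      standard_objectives(scfa = bundle$shared[[1]],
                          feed = names(bundle$diet),
                          gases = bundle$shared[[1]],
                          sugars = bundle$shared[[1]])
    member_queries <- unlist(lapply(names(post_cm$members), function(k)
      paste0(k, ":", names(post_cm$members[[k]]$reactions))))
    suite_post <- run_objective_suite(post_cm, specs,
                                      queries = member_queries,
                                      method = method)
    pre_queries <- unlist(lapply(names(cm$members), function(k)
      paste0(k, ":", names(cm$members[[k]]$reactions))))
    suite_pre <- run_objective_suite(cm, specs, queries = pre_queries,
                                     method = method)
    ok <- function(s) Filter(function(r) is.null(r$error), s$runs)
    shift <- flux_shift(lapply(ok(suite_pre), `[[`, "fva"),
                        lapply(ok(suite_post), `[[`, "fva"))
    rob <- robustness_stats(suite_post, members = names(post_cm$members))
    dens <- density_summary(c(rob$table$sd_min, rob$table$sd_max))
    results$suite <<- suite_post
    results$flux_shift <<- shift
    results$robustness <<- rob
    c(basename(write_tsv(shift$table, file.path(out, "flux_shift.tsv"))),
      basename(write_tsv(rob$table, file.path(out, "robustness.tsv"))),
      basename(write_tsv(rob$summary,
                         file.path(out, "robustness_summary.tsv"))),
      basename(write_tsv(dens, file.path(out, "sd_density.csv"))))
  })

  invisible(list(manifest = manifest, results = results, out_dir = out))
}
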