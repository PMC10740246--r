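# Pipeline orchestration: a single structured configuration holding the
# study's fixed constants, and idempotent stages that exchange artifacts on
# disk (SDF ensembles, TSV tables, JSON reports).

#' Pipeline configuration
#'
#' All defaults are the study's constants: ensembles of up to 250
#' conformers, bioactive-like/non-bioactive thresholds at 1.0/2.5 Angstrom,
#' 80/10/10 splits replicated 5 times, BEDROC alpha 20, hard-subset rule of
#' a full ensemble with under 5 percent bioactive-like conformers, and a
#' selection-fraction grid of 1/5/20/100 percent.
#'
#' @param out_dir artifact directory.
#' @param seed master seed fanned out to every stage.
#' @param max_conformers generation budget per molecule.
#' @param bio_like,non_bio labelling thresholds (Angstrom).
#' @param split_type `"random"` or `"scaffold"`.
#' @param split_ratios train/val/test fractions.
#' @param n_replicates number of split replicates.
#' @param alpha BEDROC exponent.
#' @param hard_max_n,hard_frac hard-subset definition.
#' @param fractions top-fraction grid for conformer selection.
#' @param rankers ranker names to run at the `rank` stage.
#' @param model,train [model_config()] and [train_config()] for the
#'   network stages.
#' @param synth [synthetic_spec()] used by the `synth` stage.
#' @return List of class `cb_config`.
#' @export
pipeline_config <- function(out_dir = "confbias_run", seed = 1L,
                            max_conformers = 250L,
                            bio_like = 1.0, non_bio = 2.5,
                            split_type = "random",
                            split_ratios = c(0.8, 0.1, 0.1),
                            n_replicates = 5L, alpha = 20,
                            hard_max_n = 250L, hard_frac = 0.05,
                            fractions = c(0.01, 0.05, 0.20, 1.0),
                            rankers = c("random", "generator_order", "energy",
                                        "sasa", "rgyr", "tfd2simrefmcs",
                                        "oracle"),
                            model = model_config(preset = "desk"),
                            train = train_config(),
                            synth = synthetic_spec()) {
  stopifnot(bio_like > 0, non_bio > bio_like,
            abs(sum(split_ratios) - 1) < 1e-9)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 max_conformers = as.integer(max_conformers),
                 bio_like = bio_like, non_bio = non_bio,
                 split_type = split_type, split_ratios = split_ratios,
                 n_replicates = as.integer(n_replicates), alpha = alpha,
                 hard_max_n = as.integer(hard_max_n), hard_frac = hard_frac,
                 fractions = fractions, rankers = rankers,
                 model = model, train = train, synth = synth),
            class = "cb_config")
}

.cb_artifact <- function(config, name) file.path(config$out_dir, name)

.cb_require_artifact <- function(config, name, producer) {
  path <- .cb_artifact(config, name)
  if (!file.exists(path))
    stop("missing artifact '", name, "'; run stage '", producer, "' first")
  path
}

.cb_load_ensembles <- function(config) {
  path <- .cb_require_artifact(config, "ensembles.sdf", "synth")
  raw <- read_sdf_ensembles(path)
  lab <- utils::read.delim(.cb_require_artifact(config, "labels.tsv", "label"))
  out <- list()
  for (id in names(raw)) {
    confs <- raw[[id]]$conformers
    gen <- Filter(function(cf) cf$source == "generated", confs)
    bio <- Filter(function(cf) cf$source == "bioactive", confs)
    ens <- build_labelled_ensemble(raw[[id]]$mol, gen, bio,
                                   config$bio_like, config$non_bio)
    fam <- lab$group[match(id, lab$mol_id)]
    ens$family <- if (length(fam)) fam else NA_character_
    out[[id]] <- ens
  }
  out
}

.cb_stage_synth <- function(config) {
  bench <- make_benchmark(config$synth)
  write_sdf_ensembles(bench$ensembles, .cb_artifact(config, "ensembles.sdf"))
  utils::write.table(
    data.frame(bench$class_labels,
               retrieved = vapply(bench$ensembles, function(e) e$retrieved, TRUE),
               n_conformers = vapply(bench$ensembles,
                                     function(e) length(e$labels), 0L)),
    .cb_artifact(config, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_molecule_table(lapply(bench$ensembles, function(e) e$mol),
                       .cb_artifact(config, "molecules.tsv"))
  if (length(bench$flags))
    writeLines(bench$flags, .cb_artifact(config, "synth_flags.log"))
  invisible(bench)
}

.cb_stage_split <- function(config) {
  ens <- .cb_load_ensembles(config)
  mols <- lapply(ens, function(e) e$mol)
  weights <- vapply(ens, function(e) length(e$labels), 0)
  splits <- lapply(seq_len(config$n_replicates), function(r) {
    s <- derive_seed(config$seed, r)
    if (config$split_type == "scaffold")
      scaffold_split(mols, weights, config$split_ratios, seed = s)
    else random_split(names(ens), config$split_ratios, seed = s)
  })
  write_split_table(splits, .cb_artifact(config, "splits.tsv"))
  invisible(splits)
}

.cb_stage_train <- function(config) {
  ens <- .cb_load_ensembles(config)
  splits <- utils::read.delim(.cb_require_artifact(config, "splits.tsv", "split"))
  s1 <- splits[splits$seed == min(splits$seed), ]
  tr <- ens[s1$mol_id[s1$subset == "train"]]
  va <- ens[s1$mol_id[s1$subset == "val"]]
  train_ds <- atnn_dataset(tr, config$model, max_per_mol = 25L,
                           seed = config$seed)
  val_ds <- atnn_dataset(va, config$model, max_per_mol = 25L,
                         seed = config$seed)
  model <- atnn_train(train_ds, val_ds, config$model, config$train)
  atnn_save(model, .cb_artifact(config, "model.rds"))
  write_training_history(model, .cb_artifact(config, "history.tsv"))
  invisible(model)
}

.cb_stage_rank <- function(config) {
  ens <- .cb_load_ensembles(config)
  splits <- utils::read.delim(.cb_require_artifact(config, "splits.tsv", "split"))
  s1 <- splits[splits$seed == min(splits$seed), ]
  test_ids <- s1$mol_id[s1$subset == "test"]
  refs <- ens[s1$mol_id[s1$subset == "train"]]
  model <- if ("atnn" %in% config$rankers)
    atnn_load(.cb_require_artifact(config, "model.rds", "train"))
  rankings <- list()
  for (id in test_ids) {
    e <- ens[[id]]
    for (rname in config$rankers) {
      rk <- switch(rname,
                   random = rank_random(e, seed = derive_seed(config$seed,
                                                              match(id, test_ids))),
                   generator_order = rank_generator_order(e),
                   energy = rank_energy(e),
                   sasa = rank_sasa(e),
                   rgyr = rank_rgyr(e),
                   oracle = rank_oracle(e),
                   tfd2simrefmcs = rank_tfd2simrefmcs(e, refs),
                   atnn = predict_and_rank(e, model),
                   stop("unknown ranker: ", rname))
      if (is.null(rk)) next   # per-molecule skip (e.g. force-field typing)
      rankings[[length(rankings) + 1L]] <- rk
    }
  }
  write_ranking_table(rankings, .cb_artifact(config, "rankings.tsv"))
  invisible(rankings)
}

.cb_stage_evaluate <- function(config) {
  ens <- .cb_load_ensembles(config)
  tab <- utils::read.delim(.cb_require_artifact(config, "rankings.tsv", "rank"))
  rankings <- lapply(split(tab, interaction(tab$mol_id, tab$ranker, drop = TRUE)),
                     function(d) {
                       d <- d[order(d$rank), ]
                       ranking_result(d$mol_id[1], d$ranker[1], d$conf_id,
                                      d$score)
                     })
  groups <- data.frame(mol_id = names(ens),
                       group = vapply(ens, function(e)
                         if (is.null(e$family)) NA_character_
                         else as.character(e$family), ""))
  report <- evaluate_rankings(ens, rankings, alpha = config$alpha,
                              hard_max_n = config$hard_max_n,
                              hard_frac = config$hard_frac, groups = groups)
  utils::write.table(report, .cb_artifact(config, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarize_eval(report)
  jsonlite::write_json(summ, .cb_artifact(config, "evaluation_summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run one pipeline stage
#'
#' Stages: `synth` (synthetic benchmark to disk), `label` (alias of synth's
#' labelling output for externally supplied ensembles), `split`, `train`,
#' `rank`, `evaluate`. Each stage reads its upstream artifacts from
#' `config$out_dir`, fails with an actionable message naming the producing
#' stage when they are absent, and is idempotent given identical inputs and
#' seeds. A manifest of the configuration and stage completions is kept in
#' `manifest.json`.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return The stage's main in-memory artifact, invisibly.
#' @export
run_stage <- function(stage = c("synth", "label", "split", "train", "rank",
                                "evaluate"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(stage,
                synth = .cb_stage_synth(config),
                label = .cb_stage_synth(config),
                split = .cb_stage_split(config),
                train = .cb_stage_train(config),
                rank = .cb_stage_rank(config),
                evaluate = .cb_stage_evaluate(config))
  manifest_path <- .cb_artifact(config, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  manifest$seed <- config$seed
  manifest$stages[[stage]] <- list(done = TRUE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(res)
}
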