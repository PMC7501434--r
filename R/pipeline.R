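#' Default pipeline configuration
#'
#' Desk-scale defaults (small cohort, reduced permutation counts) suitable
#' for interactive use and testing; `paperScale = TRUE` switches to the
#' full study design: 44 patients vs 100 controls, 30 nodes, 200 rest /
#' 152 task frames, 100 balanced-subsampling iterations and 10,000
#' permutations.
#'
#' @param paperScale use the full study-scale settings.
#' @return named list of configuration values.
#' @export
defaultRunConfig <- function(paperScale = FALSE) {
  cfg <- list(
    n_patients = 20L, n_controls = 20L, n_nodes = 10L,
    frames = c(rest = 200L, L1 = 152L, L2 = 152L),
    sparsity = 0.1,
    lambda = NULL,                    # NULL = per-run CV selection
    lambda_grid = lambdaGrid(),
    cv_folds = 5L,
    n_subsample = 25L,
    n_perm = 100L,
    fdr_q = 0.05,
    seed = 1L,
    out_dir = "fcnet-run")
  if (paperScale) {
    cfg$n_patients <- 44L
    cfg$n_controls <- 100L
    cfg$n_nodes <- 30L
    cfg$n_subsample <- 100L
    cfg$n_perm <- 10000L
  }
  cfg
}

#' Read a configuration file (YAML key-value) over the defaults
#'
#' @param path YAML file; keys override [defaultRunConfig()] values.
#' @param paperScale base preset.
#' @return configuration list.
#' @export
readRunConfig <- function(path, paperScale = FALSE) {
  cfg <- defaultRunConfig(paperScale)
  user <- yaml::read_yaml(path)
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (!is.null(cfg$frames)) cfg$frames <- unlist(cfg$frames)
  cfg
}

.writeTableWithHeader <- function(tab, path, hdr) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

.configHash <- function(cfg) {
  cfg$out_dir <- NULL                   # hash the scientific config only
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg[order(names(cfg))], file = tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(manifest, name, expr, log) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  dt <- proc.time()[["elapsed"]] - t0
  msg <- sprintf("[%s] %.2fs", name, dt)
  message(msg)
  cat(msg, "\n", file = log, append = TRUE)
  manifest$timings[[name]] <- dt
  list(manifest = manifest, result = res)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> network estimation -> classification -> edgewise ANOVA ->
#' SDSA, writing every stage's table under `config$out_dir` together with a
#' run manifest (config snapshot, per-file checksums, stage timings). All
#' numeric tables embed the config hash in a `#` header line; a rerun with
#' the same config and seed reproduces identical files.
#'
#' @param config list from [defaultRunConfig()] / [readRunConfig()].
#' @return the manifest, invisibly (also written as `manifest.yaml`).
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  stopifnot(config$n_patients > 0, config$n_controls > 0,
            config$n_nodes > 1)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$out_dir, "run.log")
  cat(sprintf("fcnet run, seed %d\n", config$seed), file = log)
  hash <- .configHash(config)
  hdr <- c(sprintf("config_hash: %s", hash),
           sprintf("seed: %d", config$seed),
           sprintf("fcnet_version: %s",
                   as.character(utils::packageVersion("fcnet"))))
  manifest <- list(config = config, config_hash = hash,
                   version = as.character(utils::packageVersion("fcnet")),
                   files = list(), timings = list())

  st <- .stage(manifest, "simulate", {
    model <- makeGroundTruth(nNodes = config$n_nodes,
                             sparsity = config$sparsity,
                             effects = defaultEffectSpec(config$n_nodes),
                             seed = config$seed)
    cohort <- generateCohort(model, config$n_patients, config$n_controls,
                             frames = config$frames, seed = config$seed)
    writeCohort(cohort, file.path(config$out_dir, "timeseries"))
    list(model = model, cohort = cohort)
  }, log)
  manifest <- st$manifest
  model <- st$result$model
  cohort <- st$result$cohort

  st <- .stage(manifest, "netmats", {
    ee <- cohortEdges(cohort, lambda = config$lambda,
                      grid = config$lambda_grid, folds = config$cv_folds)
    writeEdgeTable(ee, file.path(config$out_dir, "edges.csv"),
                   headerLines = hdr)
    ee
  }, log)
  manifest <- st$manifest
  ee <- st$result

  st <- .stage(manifest, "classify", {
    condDs <- conditionDataset(ee)
    condRep <- losoCv(condDs, task = "condition")
    condPerm <- permutationTest(condDs, meanAccuracy(condRep),
                                config$n_perm, seed = config$seed,
                                classifierRunner = function(d)
                                  meanAccuracy(losoCv(d, task = "condition")),
                                scheme = "condition")
    condRep <- withPermutationP(condRep, condPerm)

    grpDs <- groupDataset(ee, condition = "rest")
    grpRep <- balancedGroupClassification(grpDs, config$n_subsample,
                                          seed = config$seed)
    nPat <- sum(grpDs@y == "patient")
    grpPerm <- permutationTest(grpDs, meanAccuracy(grpRep), config$n_perm,
                               seed = config$seed,
                               classifierRunner = function(d) {
                                 pick <- sort(c(which(d@y == "patient"),
                                                sample(which(d@y == "control"),
                                                       nPat)))
                                 meanAccuracy(losoCv(.subsetDataset(d, pick),
                                                     task = "group"))
                               }, scheme = "group")
    grpRep <- withPermutationP(grpRep, grpPerm)

    tab <- rbind(
      data.frame(task = "condition",
                 class = names(perClassAccuracy(condRep)),
                 accuracy = unname(perClassAccuracy(condRep)),
                 p_perm = permutationP(condRep),
                 n_perm = condRep@nPermutations, seed = config$seed),
      data.frame(task = "group_rest",
                 class = names(perClassAccuracy(grpRep)),
                 accuracy = unname(perClassAccuracy(grpRep)),
                 p_perm = permutationP(grpRep),
                 n_perm = grpRep@nPermutations, seed = config$seed))
    .writeTableWithHeader(tab, file.path(config$out_dir,
                                         "classification.csv"), hdr)
    list(condition = condRep, group = grpRep)
  }, log)
  manifest <- st$manifest
  reports <- st$result

  st <- .stage(manifest, "anova", {
    tab <- edgewiseAnova(ee, q = config$fdr_q)
    .writeTableWithHeader(tab, file.path(config$out_dir,
                                         "edgewise_anova.csv"), hdr)
    tab
  }, log)
  manifest <- st$manifest

  st <- .stage(manifest, "sdsa", {
    sdsa <- cohortSdsa(cohort)
    tab <- nodewiseSdsaAnova(sdsa, q = config$fdr_q)
    .writeTableWithHeader(tab, file.path(config$out_dir,
                                         "sdsa_anova.csv"), hdr)
    .writeTableWithHeader(sdsa, file.path(config$out_dir, "sdsa.csv"), hdr)
    tab
  }, log)
  manifest <- st$manifest

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir,
                                    c("run.log", "manifest.yaml")))
  sums <- tools::md5sum(files)
  manifest$files <- as.list(setNames(unname(sums),
                                     sub(paste0("^", config$out_dir, "/?"),
                                         "", files)))
  manifest$reports <- list(
    condition_accuracy = meanAccuracy(reports$condition),
    condition_p = permutationP(reports$condition),
    group_accuracy = meanAccuracy(reports$group),
    group_p = permutationP(reports$group))
  cfgOut <- manifest$config
  cfgOut$lambda_grid <- as.numeric(cfgOut$lambda_grid)
  cfgOut$frames <- as.list(cfgOut$frames)
  manifest$config <- cfgOut
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Write the small deterministic fixture bundle used by the tests
#'
#' A 2-node model, a 5-node chain-graph cohort, a 4-subject ANOVA instance
#' and a toy volume set, all pure functions of `seed`.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return invisibly, the list of objects written.
#' @export
makeFixtures <- function(dir, seed = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  anova4 <- matrix(round(rnorm(12, mean = 10, sd = 2), 3), 4, 3,
                   dimnames = list(NULL, .CONDITIONS))
  write.csv(data.frame(subject = paste0("S", 1:4),
                       group = c("patient", "patient", "control", "control"),
                       anova4),
            file.path(dir, "anova4.csv"), row.names = FALSE)

  m2 <- makeGroundTruth(nNodes = 2, sparsity = 0.4,
                        effects = defaultEffectSpec(2, nConditionEdges = 0,
                                                    groupEdge = c(1, 2),
                                                    nSdsaNodes = 0),
                        seed = seed + 1)
  ch2 <- generateCohort(m2, 2, 2, frames = c(rest = 30, L1 = 20, L2 = 20),
                        seed = seed + 1)
  writeCohort(ch2, file.path(dir, "cohort2"))

  m5 <- makeGroundTruth(nNodes = 5, sparsity = 0.3, seed = seed + 2)
  ch5 <- generateCohort(m5, 2, 2, frames = c(rest = 60, L1 = 40, L2 = 40),
                        seed = seed + 2)
  writeCohort(ch5, file.path(dir, "cohort5"))

  maps <- matrix(rnorm(60 * 5), 60, 5)
  mask <- as.numeric(seq_len(60) <= 8)
  tvs <- makeToyVolumes(maps, ch5, lesion = list(mask = mask, amplitude = 1),
                        noiseSd = 0.1, seed = seed + 3)
  writeToyVolumes(tvs, file.path(dir, "volumes"))

  invisible(list(anova4 = anova4, cohort2 = ch2, cohort5 = ch5,
                 volumes = tvs))
}
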