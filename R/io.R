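## File readers/writers and the end-to-end pipeline.

#' Read a snapshot from CSV/TSV, Matrix Market or h5ad
#'
#' Dense CSV/TSV: cells in rows, header of feature names, first column
#' `cell_id`.  Matrix Market: a cells-by-features `.mtx` with sidecar files
#' `<stem>.cells.txt` and `<stem>.features.txt` (one id per line).  h5ad:
#' converted through the `anndata` package of a `python` interpreter on the
#' `PATH` (the main matrix layer is read as counts).
#'
#' @param path input file.
#' @param format `"auto"` (from the extension) or one of `"csv"`, `"tsv"`,
#'   `"mtx"`, `"h5ad"`.
#' @param embedding logical: mark the values as coordinates rather than
#'   counts.
#' @return A [Snapshot-class].
#' @export
readSnapshot <- function(path, format = c("auto", "csv", "tsv", "mtx",
                                          "h5ad"),
                         embedding = FALSE) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                         mtx = "mtx", h5ad = "h5ad",
                         stop("unrecognized snapshot format: .", ext))
    }
    if (!file.exists(path)) stop("file not found: ", path)
    if (format %in% c("csv", "tsv")) {
        df <- utils::read.table(path, header = TRUE,
                                sep = if (format == "csv") "," else "\t",
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
        if (ncol(df) < 2L || colnames(df)[1L] != "cell_id")
            stop("malformed snapshot file: first column must be 'cell_id'")
        ids <- as.character(df[[1L]])
        if (anyDuplicated(ids))
            stop("duplicate cell ids at rows: ",
                 paste(utils::head(which(duplicated(ids)), 5L),
                       collapse = ", "))
        m <- as.matrix(df[, -1L, drop = FALSE])
        if (!is.numeric(m) || !all(is.finite(m))) {
            bad <- which(!is.finite(m), arr.ind = TRUE)
            stop("non-finite entries, e.g. row ", bad[1L, 1L], " column ",
                 colnames(m)[bad[1L, 2L]])
        }
        return(Snapshot(m, cellIds = ids, isEmbedding = embedding))
    }
    if (format == "mtx") {
        stem <- sub("\\.mtx$", "", path)
        cellsFile <- paste0(stem, ".cells.txt")
        featFile <- paste0(stem, ".features.txt")
        if (!file.exists(cellsFile) || !file.exists(featFile))
            stop("sidecar files missing: expected ", cellsFile, " and ",
                 featFile)
        m <- as.matrix(Matrix::readMM(path))
        ids <- readLines(cellsFile)
        feats <- readLines(featFile)
        if (nrow(m) != length(ids) || ncol(m) != length(feats))
            stop("matrix dimensions do not match sidecar files")
        colnames(m) <- feats
        return(Snapshot(m, cellIds = ids, isEmbedding = embedding))
    }
    ## h5ad via python/anndata
    py <- Sys.which("python")
    if (py == "")
        stop("reading h5ad requires a 'python' interpreter with the ",
             "anndata package on the PATH")
    tmp <- tempfile("h5ad")
    dir.create(tmp)
    script <- paste(
        "import sys, anndata, scipy.sparse as sp, scipy.io as sio, numpy as np",
        "ad = anndata.read_h5ad(sys.argv[1])",
        "X = ad.X if sp.issparse(ad.X) else sp.csr_matrix(np.asarray(ad.X))",
        "sio.mmwrite(sys.argv[2] + '/m.mtx', X)",
        "open(sys.argv[2] + '/m.cells.txt', 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')",
        "open(sys.argv[2] + '/m.features.txt', 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')",
        sep = "; ")
    status <- system2(py, c("-c", shQuote(script), shQuote(path),
                            shQuote(tmp)), stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(status, "status")))
        stop("h5ad conversion failed: ", paste(status, collapse = "\n"))
    on.exit(unlink(tmp, recursive = TRUE))
    readSnapshot(file.path(tmp, "m.mtx"), format = "mtx",
                 embedding = embedding)
}

#' Read a cell-roles table into a StatePartition
#'
#' CSV with columns `cell_id`, `role` (one of `initial`, `intermediate`,
#' `terminal`) and `fate_label` (required exactly for terminal rows).
#' Cells of the snapshot not listed default to intermediate.
#'
#' @param path roles CSV.
#' @param snapshot the [Snapshot-class] the roles refer to.
#' @return A [StatePartition-class].
#' @export
readRoles <- function(path, snapshot) {
    stopifnot(is(snapshot, "Snapshot"))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "role")
    if (!all(need %in% colnames(df)))
        stop("roles file must have columns cell_id and role")
    if (!"fate_label" %in% colnames(df)) df$fate_label <- NA_character_
    df$fate_label[!is.na(df$fate_label) & df$fate_label == ""] <-
        NA_character_
    badRole <- which(!df$role %in% c("initial", "intermediate", "terminal"))
    if (length(badRole))
        stop("invalid role '", df$role[badRole[1L]], "' at row ",
             badRole[1L])
    missing <- which(!df$cell_id %in% snapshot@cellIds)
    if (length(missing))
        stop("cell_id not in snapshot at row ", missing[1L], ": ",
             df$cell_id[missing[1L]])
    noFate <- which(df$role == "terminal" & is.na(df$fate_label))
    if (length(noFate))
        stop("terminal row without fate_label at row ", noFate[1L])
    term <- df[df$role == "terminal", , drop = FALSE]
    init <- df$cell_id[df$role == "initial"]
    if (!length(init)) stop("roles file designates no initial cells")
    statePartition(snapshot@cellIds, initial = init,
                   terminal = term$cell_id, fateOf = term$fate_label)
}

#' Export stagewise plans as Matrix Market files plus a JSON report
#'
#' Writes `mtilde_<t>.mtx` / `mhat_<t>.mtx` (stage indices from 0) and
#' `solve_report.json` into `dir`.
#'
#' @param plans a [StagePlans-class].
#' @param report the matching [SolveReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportPlans <- function(plans, report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_along(plans@Mtilde))
        Matrix::writeMM(Matrix::Matrix(plans@Mtilde[[s]], sparse = TRUE),
                        file.path(dir, sprintf("mtilde_%d.mtx", s - 1L)))
    for (s in seq_along(plans@Mhat))
        Matrix::writeMM(Matrix::Matrix(plans@Mhat[[s]], sparse = TRUE),
                        file.path(dir, sprintf("mhat_%d.mtx", s - 1L)))
    jsonlite::write_json(.reportAsList(report),
                         file.path(dir, "solve_report.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

.reportAsList <- function(report) {
    list(converged = report@converged,
         inner_iterations = report@innerIterations,
         prox_steps_done = report@proxStepsDone,
         final_residual = report@finalResidual,
         transport_cost = report@transportCost,
         effective_epsilon = report@effectiveEpsilon)
}

.configAsList <- function(config) {
    list(n_stages = config@nStages, epsilon_start = config@epsilonStart,
         prox_iters = config@proxIters, tol = config@tolTau,
         max_inner_iters = config@maxInnerIters,
         aux_cost_Q = config@auxCostQ, seed = config@seed,
         log_domain = config@logDomain)
}

#' Run the full inference pipeline
#'
#' Chains preprocessing, embedding, cost construction and normalization,
#' optional auxiliary-state augmentation, disjoint subsetting, the
#' multistage solve, and all downstream analyses; writes result files and a
#' run manifest.  When `subsets > 1` each subset is solved independently
#' and the per-cell results pooled (pseudotime is re-normalized jointly
#' over the pooled raw mean stages).
#'
#' Output files in `outDir`: `pseudotime.csv`, `fate_probabilities.csv`,
#' `stage_distributions.csv`, `outliers.csv` (auxiliary mode only),
#' `transitions_<subset>.mtx` with a `.cells.txt` sidecar, `report.json`
#' and `manifest.json`.  Result CSVs are written with fixed numeric
#' formatting, so identical inputs give byte-identical outputs.
#'
#' @param input a [Snapshot-class] or a file path for [readSnapshot()].
#' @param roles a [StatePartition-class] or a roles CSV path.
#' @param outDir output directory.
#' @param config an [MsotConfig-class].
#' @param nComponents principal components kept for expression input.
#' @param subsets number of disjoint subsets.
#' @param embedding when `input` is a path: read values as coordinates.
#' @param seed seed for subsetting.
#' @return Invisibly, `list(pseudotime, fates, entropy, outliers, reports,
#'   manifest)`.
#' @export
runPipeline <- function(input, roles, outDir, config = msotConfig(),
                        nComponents = 50L, subsets = 1L, embedding = FALSE,
                        seed = 0L) {
    t0 <- Sys.time()
    snapshot <- if (is(input, "Snapshot")) input
                else readSnapshot(input, embedding = embedding)
    partition <- if (is(roles, "StatePartition")) roles
                 else readRoles(roles, snapshot)
    emb <- if (snapshot@isEmbedding) snapshot
           else pcaEmbed(preprocessCounts(snapshot),
                         nComponents = min(nComponents,
                                           dim(snapshot@values)))
    parts <- partitionSubsets(emb, partition, subsets, seed = seed)

    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    useAux <- !is.na(config@auxCostQ)
    ptList <- list(); fateList <- list(); stageList <- list()
    outlierList <- list(); reports <- list()
    for (i in seq_along(parts)) {
        subEmb <- parts[[i]]$snapshot
        subPart <- parts[[i]]$partition
        costs <- normalizeCosts(computeCosts(subEmb, subPart))
        if (useAux) {
            aug <- augmentAuxiliary(costs, subPart, Q = config@auxCostQ)
            costs <- aug$costs; subPart <- aug$partition
        }
        fit <- proximalSolve(costs, subPart, config)
        reports[[i]] <- fit$report
        stages <- stageDistributions(fit$plans, subPart)
        ptList[[i]] <- msotPseudotime(stages, subPart)
        model <- aggregateTransitions(fit$plans, subPart)
        fates <- fateProbabilities(model, subPart)
        keep <- setdiff(rownames(fates), .auxIds)
        fateList[[i]] <- fates[keep, , drop = FALSE]
        stageList[[i]] <- stages[keep, , drop = FALSE]
        if (useAux)
            outlierList[[i]] <- flagOutliers(fates)
        Matrix::writeMM(Matrix::Matrix(model@A, sparse = TRUE),
                        file.path(outDir,
                                  sprintf("transitions_%d.mtx", i)))
        writeLines(cellIds(model),
                   file.path(outDir,
                             sprintf("transitions_%d.cells.txt", i)))
    }

    ## pool by cell id, restore snapshot order, joint pseudotime rescale
    pt <- do.call(rbind, ptList)
    pt <- pt[match(snapshot@cellIds, pt$cell_id), , drop = FALSE]
    rng <- range(pt$raw_mean_stage)
    pt$pseudotime <- if (rng[2] > rng[1])
        (pt$raw_mean_stage - rng[1]) / (rng[2] - rng[1]) else 0
    fates <- do.call(rbind, fateList)
    fates <- fates[match(snapshot@cellIds, rownames(fates)), ,
                   drop = FALSE]
    stages <- do.call(rbind, stageList)
    stages <- stages[match(snapshot@cellIds, rownames(stages)), ,
                     drop = FALSE]

    writeResultCsv(pt, file.path(outDir, "pseudotime.csv"))
    writeResultCsv(data.frame(cell_id = rownames(fates),
                              as.data.frame(fates), check.names = FALSE),
                   file.path(outDir, "fate_probabilities.csv"))
    writeResultCsv(data.frame(cell_id = rownames(stages),
                              as.data.frame(stages), check.names = FALSE),
                   file.path(outDir, "stage_distributions.csv"))
    outliers <- NULL
    if (useAux) {
        ov <- unlist(outlierList)
        ov <- ov[match(snapshot@cellIds, names(ov))]
        outliers <- data.frame(cell_id = names(ov), outlier = unname(ov))
        writeResultCsv(outliers, file.path(outDir, "outliers.csv"))
    }
    jsonlite::write_json(lapply(reports, .reportAsList),
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(
        package_version = as.character(utils::packageVersion("msot")),
        timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        subsets = subsets,
        n_components = nComponents,
        config = .configAsList(config),
        inputs = list(
            snapshot = if (is.character(input))
                list(path = input,
                     md5 = unname(tools::md5sum(input))) else "in-memory",
            roles = if (is.character(roles))
                list(path = roles,
                     md5 = unname(tools::md5sum(roles))) else "in-memory"),
        reports = lapply(reports, .reportAsList))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(pseudotime = pt, fates = fates, stages = stages,
                   outliers = outliers, reports = reports,
                   manifest = manifest))
}

#' Read a pipeline configuration file
#'
#' YAML file mirroring the command-line flags of the `msot` script
#' (`stages`, `epsilon`, `prox_iters`, `tol`, `max_inner_iters`,
#' `aux_cost`, `log_domain`, `pcs`, `subsets`, `seed`).  Unknown keys are
#' rejected; flags given on the command line override file values.
#'
#' @param path YAML file.
#' @return `list(config = MsotConfig, nComponents =, subsets =, seed =)`.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    known <- c("stages", "epsilon", "prox_iters", "tol", "max_inner_iters",
               "aux_cost", "log_domain", "pcs", "subsets", "seed")
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]]
                                   else default
    list(config = msotConfig(
             nStages = pick("stages", 21L),
             epsilonStart = pick("epsilon", 0.05),
             proxIters = pick("prox_iters", 10L),
             tol = pick("tol", 1e-4),
             maxInnerIters = pick("max_inner_iters", 50000L),
             auxCostQ = pick("aux_cost", NA_real_),
             seed = pick("seed", 0L),
             logDomain = isTRUE(pick("log_domain", FALSE))),
         nComponents = as.integer(pick("pcs", 50L)),
         subsets = as.integer(pick("subsets", 1L)),
         seed = as.integer(pick("seed", 0L)))
}
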