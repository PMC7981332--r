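# Reading and writing cohorts: CSV phenotypes, CSV feature matrices,
# YAML configuration, optional NIfTI ingestion.

#' Write a cohort to disk
#'
#' Phenotypes go to `phenotypes.csv` (one header row, UTF-8, '.' decimal),
#' features to `features.csv` (subject_id column plus one column per
#' feature), and the simulation configuration, when present, to
#' `config.yaml`.
#'
#' @param cohort a [BrainAgeCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "BrainAgeCohort"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    phPath <- file.path(dir, "phenotypes.csv")
    fePath <- file.path(dir, "features.csv")
    utils::write.csv(phenotypes(cohort), phPath, row.names = FALSE,
        fileEncoding = "UTF-8")
    fe <- data.frame(subject_id = colnames(cohort),
        gmFeatures(cohort), check.names = FALSE)
    utils::write.csv(fe, fePath, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(phenotypes = phPath, features = fePath)
    cfg <- S4Vectors::metadata(cohort)$config
    if (!is.null(cfg)) {
        cfgPath <- file.path(dir, "config.yaml")
        yaml::write_yaml(configAsList(cfg), cfgPath)
        paths <- c(paths, config = cfgPath)
    }
    invisible(paths)
}

configAsList <- function(config) {
    list(nSubjects = config@nSubjects, seed = config@seed,
        ageRange = config@ageRange, propMale = config@propMale,
        lifestyle = cbind(variable = rownames(config@lifestyle),
            config@lifestyle),
        nFeatures = config@nFeatures,
        featureNoiseSd = config@featureNoiseSd,
        ageTrend = as.numeric(config@ageTrend),
        estimatorNoiseSd = config@estimatorNoiseSd)
}

#' Load a cohort from phenotype and feature files
#'
#' Reads the two CSV files, aligns them by `subject_id` (feature-file row
#' order is irrelevant), errors on orphan ids or non-numeric feature
#' cells, and drops subjects missing any field required downstream (with
#' a reported count).
#'
#' @param phenotypePath CSV with a `subject_id` column and the phenotype
#'   columns.
#' @param featurePath CSV with `subject_id` plus one column per feature.
#' @param requiredFields phenotype fields that must be non-missing; rows
#'   failing this are excluded with a message.
#' @return a [BrainAgeCohort-class].
#' @export
loadCohort <- function(phenotypePath, featurePath,
        requiredFields = c("age", "sex")) {
    for (p in c(phenotypePath, featurePath))
        if (!file.exists(p)) stop("input file not found: ", p)
    ph <- utils::read.csv(phenotypePath, fileEncoding = "UTF-8",
        stringsAsFactors = FALSE)
    fe <- utils::read.csv(featurePath, fileEncoding = "UTF-8",
        check.names = FALSE, stringsAsFactors = FALSE)
    if (!"subject_id" %in% colnames(ph) ||
            !"subject_id" %in% colnames(fe))
        stop("both files need a subject_id column")
    orphans <- c(setdiff(ph$subject_id, fe$subject_id),
        setdiff(fe$subject_id, ph$subject_id))
    if (length(orphans))
        stop("subject ids present in only one file: ",
            paste(orphans, collapse = ", "))
    featCols <- setdiff(colnames(fe), "subject_id")
    for (cn in featCols) {
        bad <- which(!is.na(fe[[cn]]) & is.na(suppressWarnings(
            as.numeric(fe[[cn]]))))
        if (length(bad))
            stop("non-numeric feature cell at row ", bad[1],
                ", column '", cn, "'")
        fe[[cn]] <- as.numeric(fe[[cn]])
    }
    ph <- ph[order(ph$subject_id), , drop = FALSE]
    fe <- fe[match(ph$subject_id, fe$subject_id), , drop = FALSE]
    ok <- complete.cases(ph[, intersect(requiredFields, colnames(ph)),
        drop = FALSE])
    if (any(!ok))
        message(sum(!ok), " subject(s) excluded due to missing values")
    ph <- ph[ok, , drop = FALSE]
    fe <- fe[ok, , drop = FALSE]
    if ("sex" %in% colnames(ph))
        ph$sex <- factor(ph$sex, levels = c("female", "male"))
    gm <- t(as.matrix(fe[, featCols, drop = FALSE]))
    colnames(gm) <- ph$subject_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(gm = gm),
        colData = S4Vectors::DataFrame(ph, row.names = ph$subject_id))
    new("BrainAgeCohort", se)
}

#' Flatten gray-matter probability NIfTI volumes into a feature matrix
#'
#' Optional ingestion path for one 3D gray-matter probability volume per
#' subject: voxels whose across-subject mean probability exceeds
#' `maskThreshold` become features. Requires the RNifti package.
#'
#' @param paths character vector of NIfTI file paths, one per subject.
#' @param subjectIds subject identifiers aligned with `paths`.
#' @param maskThreshold minimum mean GM probability for a voxel to be
#'   kept.
#' @return subjects x features matrix of GM probabilities.
#' @export
readGMFeaturesNifti <- function(paths, subjectIds = basename(paths),
        maskThreshold = 0.1) {
    if (!requireNamespace("RNifti", quietly = TRUE))
        stop("NIfTI ingestion requires the RNifti package")
    vols <- lapply(paths, function(p) as.numeric(RNifti::readNifti(p)))
    lens <- lengths(vols)
    if (length(unique(lens)) != 1L)
        stop("all volumes must share the same dimensions")
    m <- do.call(rbind, vols)
    rownames(m) <- subjectIds
    keep <- colMeans(m) > maskThreshold
    m[, keep, drop = FALSE]
}
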