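#' Construct a BehavioralTable
#'
#' Builds the package's central container from a subjects-by-variables table.
#' Non-numeric columns of a data frame input are retained as all-`NA`
#' variables flagged `isNumeric = FALSE` so that [selectVariables()] can
#' report them; purely numeric inputs are stored as given.
#'
#' @param values subjects x variables numeric matrix or data frame
#'   (subjects as rows).  `NA` entries encode missing values.
#' @param variableMeta optional data frame with one row per variable and any
#'   of the columns `category`, `isErrorMeasure`, `isComposite`,
#'   `isAdjusted` (logical flags default to `FALSE`).
#' @param confounds optional data frame with per-subject columns `age` and
#'   `gender`.
#' @param familyId optional per-subject family labels (character or factor);
#'   defaults to one singleton family per subject.
#' @return a [BehavioralTable-class] object (variables as rows, subjects as
#'   columns of the `"values"` assay).
#' @examples
#' x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("v", 1:4)))
#' bt <- BehavioralTable(x)
#' dim(bt)                     # 4 variables x 10 subjects
#' dim(behavioralValues(bt))   # 10 subjects x 4 variables
#' @export
BehavioralTable <- function(values, variableMeta = NULL, confounds = NULL,
                            familyId = NULL) {
    isNumericCol <- NULL
    if (is.data.frame(values)) {
        isNumericCol <- vapply(values, is.numeric, logical(1))
        vals <- matrix(NA_real_, nrow(values), ncol(values))
        vals[, isNumericCol] <- as.matrix(values[, isNumericCol, drop = FALSE])
        dimnames(vals) <- list(rownames(values), colnames(values))
        values <- vals
    }
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix or a data frame")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("V", seq_len(ncol(values)))
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
    nSub <- nrow(values)
    nVar <- ncol(values)

    rd <- DataFrame(row.names = colnames(values))
    rd$category <- rep("unassigned", nVar)
    rd$isErrorMeasure <- rep(FALSE, nVar)
    rd$isComposite <- rep(FALSE, nVar)
    rd$isAdjusted <- rep(FALSE, nVar)
    rd$isNumeric <- if (is.null(isNumericCol)) rep(TRUE, nVar) else isNumericCol
    if (!is.null(variableMeta)) {
        if (nrow(variableMeta) != nVar)
            stop("'variableMeta' must have one row per variable")
        for (cn in intersect(colnames(variableMeta),
                             c("category", "isErrorMeasure", "isComposite",
                               "isAdjusted")))
            rd[[cn]] <- variableMeta[[cn]]
    }

    cd <- DataFrame(row.names = rownames(values))
    if (!is.null(confounds)) {
        if (nrow(confounds) != nSub)
            stop("'confounds' must have one row per subject")
        for (cn in colnames(confounds)) cd[[cn]] <- confounds[[cn]]
    }
    cd$familyId <- if (is.null(familyId)) sprintf("fam%04d", seq_len(nSub))
                   else as.character(familyId)

    new("BehavioralTable",
        SummarizedExperiment(assays = SimpleList(values = t(values)),
                             rowData = rd, colData = cd))
}

#' Subjects-by-variables value matrix
#'
#' Returns the assay in the orientation the statistical functions consume:
#' subjects as rows, variables as columns.
#'
#' @param x a [BehavioralTable-class].
#' @return numeric matrix with `NA` marking missing entries.
#' @export
behavioralValues <- function(x) t(assay(x, "values"))

# Replace values from a subjects-by-variables matrix.
setBehavioralValues <- function(x, values) {
    assay(x, "values") <- t(values)
    x
}

#' Per-variable metadata
#'
#' @param x a [BehavioralTable-class].
#' @return a `DataFrame` with one row per variable.
#' @export
variableMeta <- function(x) rowData(x)

#' Per-subject confounds (age, gender)
#'
#' @param x a [BehavioralTable-class].
#' @return a `DataFrame` with the non-family columns of `colData`.
#' @export
confounds <- function(x) {
    cd <- colData(x)
    cd[, setdiff(colnames(cd), "familyId"), drop = FALSE]
}

#' Per-subject family identifiers
#'
#' @param x a [BehavioralTable-class].
#' @return character vector of family labels.
#' @export
familyId <- function(x) colData(x)$familyId

#' Missingness mask
#'
#' @param x a [BehavioralTable-class].
#' @return logical subjects x variables matrix, `TRUE` where missing.
#' @export
missingMask <- function(x) is.na(behavioralValues(x))

#' @describeIn BehavioralTable-class compact display with missingness and
#'   family summary.
#' @param object a `BehavioralTable`.
#' @export
setMethod("show", "BehavioralTable", function(object) {
    v <- assay(object, "values")
    cat("BehavioralTable:", nrow(object), "variables x", ncol(object),
        "subjects\n")
    cat("  missing: ", sprintf("%.2f%%", 100 * mean(is.na(v))),
        " | families: ", length(unique(familyId(object))), "\n", sep = "")
    cat("  variable categories:",
        paste(utils::head(unique(rowData(object)$category), 5),
              collapse = ", "), "\n")
})

#' Write / read a BehavioralTable as CSV plus JSON sidecar
#'
#' `writeBehavioralTable()` writes `<prefix>.csv` (subjects as rows, header
#' of variable names, first column the subject id) and `<prefix>.json`
#' holding variable metadata, confounds and family ids.
#' `readBehavioralTable()` reverses it.
#'
#' @param x a [BehavioralTable-class].
#' @param prefix file path prefix (without extension).
#' @return `writeBehavioralTable()` returns the two paths invisibly;
#'   `readBehavioralTable()` returns a `BehavioralTable`.
#' @export
writeBehavioralTable <- function(x, prefix) {
    vals <- behavioralValues(x)
    df <- data.frame(subject = rownames(vals), vals, check.names = FALSE)
    csv <- paste0(prefix, ".csv")
    jsn <- paste0(prefix, ".json")
    utils::write.csv(df, csv, row.names = FALSE)
    side <- list(variableMeta = as.data.frame(variableMeta(x)),
                 confounds = as.data.frame(confounds(x)),
                 familyId = familyId(x),
                 subjects = rownames(vals),
                 variables = colnames(vals))
    jsonlite::write_json(side, jsn, dataframe = "columns", digits = NA,
                         na = "null")
    invisible(c(csv, jsn))
}

#' @rdname writeBehavioralTable
#' @export
readBehavioralTable <- function(prefix) {
    df <- utils::read.csv(paste0(prefix, ".csv"), check.names = FALSE)
    side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$subject
    vm <- as.data.frame(side$variableMeta)
    conf <- if (length(side$confounds)) as.data.frame(side$confounds) else NULL
    BehavioralTable(vals, variableMeta = vm, confounds = conf,
                    familyId = side$familyId)
}
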