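# Endpoint labeling rules, dataset refinement and the 80/20 random split.
#
# The labeling functions encode, per toxicological endpoint, how raw
# assay evidence is reduced to a binary toxic (1) / nontoxic (0) label.
# Thresholds are strict inequalities exactly as the curation protocols
# state them ("higher than 2.3", "lower than 2000 mg/kg").

#' Endpoints supported by the labeling rules
#' @export
toxicityEndpoints <- function() {
  c("ANDROGENICITY", "SKIN_IRRITATION", "EYE_IRRITATION", "ORAL_TOXICITY",
    "MUTAGENICITY", "CARCINOGENICITY", "HEPATOTOXICITY", "ESTROGENICITY")
}

#' Label androgenicity evidence
#'
#' Toxic if the compound showed binding activity in at least one
#' competitive binding assay AND activity in at least one reporter gene
#' assay; nontoxic if the binding assay and all reporter gene assays were
#' negative; anything else is indeterminate and excluded from a dataset.
#'
#' @param bindingPositive logical, any positive competitive binding assay.
#' @param anyReporterPositive logical, any positive reporter gene assay.
#' @param allAssaysNegative logical, binding and all reporter assays
#'   negative.
#' @return integer 1 (toxic), 0 (nontoxic) or `NA` (indeterminate).
#' @export
labelAndrogenicity <- function(bindingPositive, anyReporterPositive,
                               allAssaysNegative) {
  stopifnot(is.logical(bindingPositive), is.logical(anyReporterPositive),
            is.logical(allAssaysNegative))
  n <- max(length(bindingPositive), length(anyReporterPositive),
           length(allAssaysNegative))
  if (n == 0) stop("no assay evidence supplied")
  bindingPositive <- rep_len(bindingPositive, n)
  anyReporterPositive <- rep_len(anyReporterPositive, n)
  allAssaysNegative <- rep_len(allAssaysNegative, n)
  if (any(allAssaysNegative & (bindingPositive | anyReporterPositive)))
    stop("contradictory evidence: all-negative flag with a positive assay")
  ifelse(bindingPositive & anyReporterPositive, 1L,
         ifelse(allAssaysNegative, 0L, NA_integer_))
}

#' Label skin-irritation evidence
#'
#' Toxic if the average erythema/edema score exceeds 2.3 (GHS
#' convention, strictly "higher than") or irreversible skin irritation /
#' corrosion effects were reported.
#'
#' @param avgErythemaEdemaScore non-negative average score.
#' @param irreversibleCorrosion logical.
#' @return integer 0/1 label(s).
#' @export
labelSkin <- function(avgErythemaEdemaScore, irreversibleCorrosion = FALSE) {
  if (any(avgErythemaEdemaScore < 0, na.rm = TRUE))
    stop("negative erythema/edema score")
  as.integer(avgErythemaEdemaScore > 2.3 | irreversibleCorrosion)
}

#' Label eye-irritation evidence
#'
#' Toxic if a damaging effect on the conjunctiva, cornea or iris was
#' reported after a single dose. Damage to any one tissue suffices (the
#' GHS-style reading; see the methods vignette for the rationale).
#'
#' @param conjunctivaDamage,corneaDamage,irisDamage logical flags.
#' @return integer 0/1 label(s).
#' @export
labelEye <- function(conjunctivaDamage, corneaDamage, irisDamage) {
  as.integer(conjunctivaDamage | corneaDamage | irisDamage)
}

#' Label acute-oral-toxicity evidence
#'
#' Toxic iff LD50 is strictly lower than 2000 mg/kg.
#'
#' @param ld50 lethal dose in mg/kg; must be positive.
#' @return integer 0/1 label(s).
#' @export
labelOral <- function(ld50) {
  if (any(ld50 <= 0, na.rm = TRUE)) stop("LD50 must be positive")
  as.integer(ld50 < 2000)
}

#' Remove duplicate and inconsistent records
#'
#' Collapses records to one per canonical structure; structures carrying
#' conflicting labels are removed entirely (both sides dropped, no
#' adjudication).
#'
#' @param records data.frame with columns `smiles` (canonical) and
#'   `label` (0/1); extra columns are carried along from the first
#'   occurrence.
#' @return the refined data.frame, with attribute `"report"`: a list with
#'   `nInput`, `nDuplicatesRemoved`, `nInconsistentStructures`,
#'   `nInconsistentRecords`, `nOutput`.
#' @export
refineDataset <- function(records) {
  stopifnot(is.data.frame(records), all(c("smiles", "label") %in%
                                          names(records)))
  stopifnot(all(records$label %in% c(0L, 1L)))
  labs <- tapply(records$label, records$smiles, function(x)
    if (length(unique(x)) > 1L) NA_integer_ else x[[1]])
  inconsistent <- names(labs)[is.na(labs)]
  keep <- !records$smiles %in% inconsistent &
    !duplicated(records$smiles)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(
    nInput = nrow(records),
    nDuplicatesRemoved = sum(duplicated(records$smiles) &
                               !records$smiles %in% inconsistent),
    nInconsistentStructures = length(inconsistent),
    nInconsistentRecords = sum(records$smiles %in% inconsistent),
    nOutput = nrow(out))
  out
}

#' Random 80/20 train/test split
#'
#' Plain (non-stratified) random split, reproducible given the seed.
#' Train and test are disjoint and exhaustive by row.
#'
#' @param records data.frame (typically refined `smiles`/`label`).
#' @param trainFraction proportion in the training set (default 0.8).
#' @param seed integer seed.
#' @return list with `train`, `test` (data.frames), `seed`,
#'   `trainFraction`.
#' @export
randomSplit <- function(records, trainFraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 5) stop("too few records to split (need >= 5)")
  stopifnot(trainFraction > 0, trainFraction < 1)
  nTrain <- round(nrow(records) * trainFraction)
  idx <- withSeed(seed, sample.int(nrow(records), nTrain))
  train <- records[idx, , drop = FALSE]
  test <- records[-idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, seed = as.integer(seed),
       trainFraction = trainFraction)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Read compounds from CSV or .smi
#'
#' CSV files need a `smiles` column (optional `label`, extra columns
#' kept); `.smi` files are one record per line, `SMILES[ id]`, with no
#' header.
#'
#' @param path input file.
#' @return data.frame with at least `smiles`.
#' @export
readCompounds <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t,]+")
    return(data.frame(
      smiles = vapply(parts, `[[`, character(1), 1),
      id = vapply(parts, function(p)
        if (length(p) > 1) p[[2]] else p[[1]], character(1)),
      stringsAsFactors = FALSE))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df)) {
    # headerless two-column CSV: assume smiles[,label]
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("smiles", "label")[seq_len(min(2, ncol(df)))]
  }
  if ("label" %in% names(df)) df$label <- as.integer(df$label)
  df
}

#' Write compounds to CSV
#' @param records data.frame with `smiles` (and usually `label`).
#' @param path output path.
#' @export
writeCompounds <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
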