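#' Read a STITCH-dialect chemical-chemical links file
#'
#' Parses a tab-separated `chemical_chemical.links.detailed` dump (columns
#' `chemical1`, `chemical2`, `similarity`, `experimental`, `database`,
#' `textmining`, `combined_score`) into an [interaction_table()]. Pairs with
#' `score_column` strictly greater than `min_score` are kept as interactive;
#' rows listing the same unordered pair twice (STITCH dumps list each edge
#' in both directions) are collapsed by taking the maximum score, and
#' self-interactions are dropped.
#'
#' A header row is detected by looking for non-numeric score fields in the
#' first line; a headerless file must have the standard 7-column layout.
#'
#' @param path Path to the TSV file.
#' @param score_column Which score column carries the confidence score.
#' @param min_score Exclusive lower threshold; rows with score strictly
#'   greater than this are kept. The default 0 keeps every positive-score
#'   pair.
#' @return An [interaction_table()].
#' @export
read_chemical_links <- function(path, score_column = "combined_score",
                                min_score = 0) {
  std <- c("chemical1", "chemical2", "similarity", "experimental",
           "database", "textmining", "combined_score")
  tab <- read_stitch_tsv(path, std, score_column,
                         id_cols = c("chemical1", "chemical2"))
  keep <- tab$score > min_score
  interaction_table(data.frame(chemical_a = tab$id1[keep],
                               chemical_b = tab$id2[keep],
                               score = tab$score[keep]))
}

#' Read a STITCH-dialect protein-chemical links file
#'
#' Parses a tab-separated `protein_chemical.links.detailed` dump (columns
#' `chemical`, `protein`, `experimental`, `database`, `textmining`,
#' `combined_score`) into a [protein_chemical_table()]. Duplicated
#' (chemical, protein) rows collapse by maximum score; absent pairs look up
#' as 0.
#'
#' @inheritParams read_chemical_links
#' @return A [protein_chemical_table()].
#' @export
read_protein_links <- function(path, score_column = "combined_score",
                               min_score = 0) {
  std <- c("chemical", "protein", "experimental", "database", "textmining",
           "combined_score")
  tab <- read_stitch_tsv(path, std, score_column,
                         id_cols = c("chemical", "protein"))
  keep <- tab$score > min_score
  protein_chemical_table(data.frame(chemical = tab$id1[keep],
                                    protein = tab$id2[keep],
                                    score = tab$score[keep]))
}

# Shared reader for the two STITCH dialects. Returns data.frame(id1, id2,
# score). Errors name the missing column or the offending line.
read_stitch_tsv <- function(path, std_columns, score_column, id_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  empty <- data.frame(id1 = character(), id2 = character(), score = numeric())
  if (length(first) == 0L) return(empty)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  score_fields <- fields[-seq_along(id_cols)]
  has_header <- length(score_fields) == 0L ||
    any(is.na(suppressWarnings(as.numeric(score_fields))))
  if (has_header) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = seq_along(id_cols)),
                            data.table = TRUE, showProgress = FALSE)
    if (!score_column %in% names(dt)) {
      stop("format error: column '", score_column, "' not found in ", path)
    }
    for (col in id_cols) {
      if (!col %in% names(dt)) {
        stop("format error: column '", col, "' not found in ", path)
      }
    }
  } else {
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            colClasses = list(character = seq_along(id_cols)),
                            data.table = TRUE, showProgress = FALSE)
    if (ncol(dt) != length(std_columns)) {
      stop("format error: headerless file must have the standard ",
           length(std_columns), " columns ending in '", score_column, "'")
    }
    data.table::setnames(dt, std_columns)
  }
  if (nrow(dt) == 0L) return(empty)
  score <- suppressWarnings(as.numeric(dt[[score_column]]))
  bad <- which(is.na(score) | score < 0)
  if (length(bad) > 0L) {
    stop("validation error: negative or non-numeric '", score_column,
         "' at data line ", bad[1], " of ", path)
  }
  data.frame(id1 = as.character(dt[[id_cols[1]]]),
             id2 = as.character(dt[[id_cols[2]]]),
             score = score, stringsAsFactors = FALSE)
}

#' Read a drug-to-side-effect label table
#'
#' Reads a two-column TSV of (drug identifier, side-effect identifier)
#' assignments, such as an export of SIDER drug/side-effect pairs.
#' Duplicate rows are collapsed; the first-seen order of drugs and of side
#' effects is preserved (it fixes downstream tie-breaking).
#'
#' @param path Path to the TSV file. A header row is accepted if its first
#'   field is `drug`.
#' @return data.frame with character columns `drug` and `side_effect`, one
#'   row per distinct pair.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^drug\t", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) {
    return(data.frame(drug = character(), side_effect = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    stop("format error: expected 2 tab-separated columns at line ",
         which(nfield != 2L)[1], " of ", path)
  }
  drug <- vapply(parts, `[`, character(1), 1L)
  eff <- vapply(parts, `[`, character(1), 2L)
  dup <- duplicated(paste(drug, eff, sep = "\r"))
  data.frame(drug = drug[!dup], side_effect = eff[!dup],
             stringsAsFactors = FALSE)
}

#' Read a .smi SMILES file
#'
#' One molecule per line: a SMILES string, whitespace, then the identifier.
#' Blank lines and lines starting with `#` are skipped. Duplicate
#' identifiers keep the last occurrence with a warning.
#'
#' @param path Path to the .smi file.
#' @return Named character vector mapping drug identifier to SMILES string.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) < 2L)) {
    stop("format error: SMILES line without an identifier: '",
         lines[which(lengths(parts) < 2L)[1]], "'")
  }
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(parts, function(p) paste(p[-1], collapse = " "), character(1))
  if (anyDuplicated(ids)) {
    warning("duplicate identifiers in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            "; keeping the last occurrence")
    keep <- !duplicated(ids, fromLast = TRUE)
    smiles <- smiles[keep]
    ids <- ids[keep]
  }
  setNames(smiles, ids)
}

#' Read a precomputed pairwise similarity table
#'
#' Three-column TSV `drug_a`, `drug_b`, `score` with similarity scores in
#' \[0, 1\]; used to feed [precomputed_provider()].
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `drug_a`, `drug_b`, `score`.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  names(df) <- c("drug_a", "drug_b", "score")
  df
}

#' Write and read ranked predictions
#'
#' `write_predictions()` serialises one or more ranked predictions to a TSV
#' with columns `drug`, `rank`, `side_effect`, `score`, `method` (the
#' evidence route used: direct, hybrid or similarity). Scores are written at
#' full double precision so the file round-trips losslessly through
#' `read_predictions()`.
#'
#' @param predictions A single ranked prediction (from [predict_two_step()]
#'   or [rank_side_effects()]) or a list of them.
#' @param path Output file path.
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns a data.frame with the columns above.
#' @export
write_predictions <- function(predictions, path) {
  if (inherits(predictions, "ranked_prediction")) {
    predictions <- list(predictions)
  }
  rows <- lapply(predictions, function(rp) {
    if (nrow(rp$ranking) == 0L) return(NULL)
    data.frame(drug = rp$drug, rank = rp$ranking$rank,
               side_effect = rp$ranking$side_effect,
               score = sprintf("%.17g", rp$ranking$score),
               method = rp$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(drug = character(), rank = integer(),
               side_effect = character(), score = character(),
               method = character()))))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "numeric", "character"))
  names(df) <- c("drug", "rank", "side_effect", "score", "method")
  df
}

#' Write and read an order-wise accuracy profile
#'
#' TSV with columns `order` (the prediction order j), `hits` (P(j), drugs
#' whose j-th ranked side effect is true), `n` (drugs evaluated) and
#' `accuracy` (AC(j) = P(j)/N, full precision). Round-trips losslessly.
#'
#' @param profile An accuracy profile from [accuracy_profile()].
#' @param path Output file path.
#' @return `write_accuracy_profile()` returns `path` invisibly;
#'   `read_accuracy_profile()` returns the profile data.frame.
#' @export
write_accuracy_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  df$accuracy <- sprintf("%.17g", df$accuracy)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_accuracy_profile
#' @export
read_accuracy_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "integer", "integer", "numeric"))
  names(df) <- c("order", "hits", "n", "accuracy")
  df
}
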