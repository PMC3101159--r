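# Output files open with a comment header recording tool version, seed and a
# short config fingerprint, so a report can always be traced to its run.
output_header <- function(seed = NA, config = NULL, extra = character()) {
  ver <- as.character(utils::packageVersion("raschcat"))
  c(paste0("# raschcat ", ver),
    paste0("# seed: ", if (is.null(seed) || is.na(seed)) "none" else seed),
    paste0("# config: ", config_hash(config)),
    extra)
}

# FNV-1a over the deparsed configuration: a stable, dependency-free
# fingerprint (not cryptographic).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = " ")
  xor32 <- function(a, b) {          # 32-bit xor on doubles
    bitwXor(a %% 65536, b %% 65536) +
      65536 * bitwXor(a %/% 65536, b %/% 65536)
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- xor32(h, b)
    # multiply mod 2^32 in 16-bit halves to stay within exact doubles
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

read_key_lines <- function(lines) {
  kv <- grep("^#\\s*[a-zA-Z_]+\\s*:", lines, value = TRUE)
  keys <- sub("^#\\s*([a-zA-Z_]+)\\s*:.*$", "\\1", kv)
  vals <- trimws(sub("^#\\s*[a-zA-Z_]+\\s*:\\s*", "", kv))
  stats::setNames(vals, keys)
}

num_or_na <- function(x) {
  bad <- !is.na(x) & x != "" & is.na(suppressWarnings(as.numeric(x)))
  if (any(bad))
    stop("malformed numeric field: ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  out <- suppressWarnings(as.numeric(x))
  out[x == "" | is.na(x)] <- NA_real_
  out
}

#' Read an item bank from delimited text
#'
#' Expects a CSV with columns
#' `item_id,label,difficulty,se,infit,outfit,status` preceded by a comment
#' block carrying the shared step calibrations
#' (`# thresholds: t1,t2,...`). Misfit rows may leave the numeric columns
#' empty; calibrated rows must parse. Malformed numeric fields and duplicate
#' ids are rejected, never coerced.
#'
#' @param path file path.
#' @return an [item_bank()].
#' @seealso [write_item_bank()], [jcq37_bank()]
#' @export
read_item_bank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- read_key_lines(lines)
  if (!"thresholds" %in% names(keys))
    stop("item bank file lacks a '# thresholds:' header line", call. = FALSE)
  thresholds <- num_or_na(strsplit(keys[["thresholds"]], ",")[[1L]])
  if (anyNA(thresholds))
    stop("non-numeric threshold in bank header", call. = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  needed <- c("item_id", "label", "difficulty", "se", "infit", "outfit", "status")
  if (!identical(names(df), needed))
    stop("item bank header must be: ", paste(needed, collapse = ","),
         call. = FALSE)
  ids <- suppressWarnings(as.integer(df$item_id))
  if (anyNA(ids)) stop("non-integer item_id", call. = FALSE)
  cal <- df$status == "calibrated"
  dif <- num_or_na(df$difficulty)
  if (any(cal & is.na(dif))) {
    bad <- which(cal & is.na(dif))[1L]
    stop("calibrated row for item ", ids[bad], " lacks a numeric difficulty",
         call. = FALSE)
  }
  item_bank(data.frame(item_id = ids, label = df$label, difficulty = dif,
                       se = num_or_na(df$se), infit = num_or_na(df$infit),
                       outfit = num_or_na(df$outfit), status = df$status,
                       stringsAsFactors = FALSE),
            rating_scale(thresholds))
}

#' Write an item bank to delimited text
#'
#' @param bank an [item_bank()].
#' @param path file path.
#' @param seed optional seed to record in the file header.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, seed = NA) {
  stopifnot(inherits(bank, "item_bank"))
  hdr <- output_header(seed, bank$scale$thresholds, extra = c(
    "# categories: 0-3 internal (survey responses 1-4 map to 0-3)",
    paste0("# thresholds: ",
           paste(format(bank$scale$thresholds, digits = 10, trim = TRUE),
                 collapse = ","))))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(bank$items, con, row.names = FALSE, quote = 2L, na = "")
  invisible(path)
}

#' Read / write a response matrix
#'
#' Delimited text, persons as rows: first column `person_id`, one column per
#' item (header = item id), integer categories, empty field = missing. The
#' header comment block states the category coding: survey-facing files use
#' the 1-based rating scale (`# coding: survey-1-based`), internal files the
#' 0-based categories (`# coding: internal-0-based`). In memory the matrix
#' is always 0-based.
#'
#' @param path file path.
#' @return integer matrix (persons x items, `NA` = missing), rownames =
#'   person ids, colnames = item ids.
#' @export
read_response_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- read_key_lines(lines)
  coding <- keys[["coding"]] %||% "internal-0-based"
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  if (names(df)[1L] != "person_id")
    stop("first column must be person_id", call. = FALSE)
  ids <- df$person_id
  vals <- as.matrix(df[-1L])
  bad <- !is.na(vals) & vals != "" &
    is.na(suppressWarnings(as.integer(vals)))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("malformed category at row ", w[1L], ", item ",
         colnames(vals)[w[2L]], call. = FALSE)
  }
  X <- matrix(suppressWarnings(as.integer(vals)), nrow = nrow(vals),
              dimnames = list(ids, colnames(vals)))
  X[is.na(vals) | vals == ""] <- NA_integer_
  if (identical(coding, "survey-1-based")) X <- X - 1L
  if (any(X < 0L, na.rm = TRUE))
    stop("category below the coding minimum", call. = FALSE)
  X
}

#' @param matrix integer response matrix (0-based categories).
#' @param coding `"survey"` writes 1-based ratings (default for
#'   survey-facing files); `"internal"` writes the 0-based categories.
#' @param seed optional seed recorded in the header.
#' @rdname read_response_matrix
#' @export
write_response_matrix <- function(matrix, path, coding = c("survey", "internal"),
                                  seed = NA) {
  coding <- match.arg(coding)
  X <- validate_response_matrix(matrix)
  out <- if (coding == "survey") X + 1L else X
  hdr <- output_header(seed, dim(X), extra = paste0(
    "# coding: ", if (coding == "survey") "survey-1-based" else "internal-0-based"))
  df <- data.frame(person_id = rownames(X), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = 1L, na = "")
  invisible(path)
}

#' Write a CAT session report
#'
#' Renders the administration log twice in one file: a human-readable
#' seven-column table (item difficulty, model probability of the observed
#' response, the response with `*` marking unexpected answers, expected
#' score, provisional measure, standard error, running outfit) as comment
#' lines, followed by a machine-readable CSV of the same steps. Session-
#' level results (final measure, SE, stop reason, outfit, aberrance) are
#' recorded as header keys so [read_session_log()] can rebuild an
#' equivalent session.
#'
#' @param session a [run_cat()] result.
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_session_report <- function(session, path, seed = NA) {
  stopifnot(inherits(session, "cat_session"))
  st <- session$steps
  fmt <- function(x, d = 2) ifelse(is.na(x), "-", formatC(x, digits = d, format = "f"))
  human <- sprintf("# %4d %10s %6s %9s %9s %9s %6s %6s",
                   st$step, fmt(st$difficulty), fmt(st$prob_observed),
                   paste0(st$response, ifelse(st$unexpected, "*", " ")),
                   fmt(st$expected_score),
                   ifelse(st$step <= session$config$burn_in, "-", fmt(st$theta)),
                   fmt(st$se), fmt(st$outfit))
  hdr <- output_header(seed, session$config, extra = c(
    sprintf("# final_theta: %.10g", session$final$theta),
    sprintf("# final_se: %.10g", session$final$se),
    paste0("# stop_reason: ", session$stop_reason),
    sprintf("# outfit: %.10g", session$outfit),
    paste0("# aberrant: ", session$aberrant),
    paste0("# thresholds: ",
           paste(format(session$scale$thresholds, digits = 10, trim = TRUE),
                 collapse = ",")),
    sprintf("# se_target: %.10g", session$config$se_target),
    paste0("# burn_in: ", session$config$burn_in),
    "# step  difficulty  prob  response  expected  measure     se outfit",
    human))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(st, digits = 10, trim = TRUE, nsmall = 0), con,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Reload a CAT session from its report file
#'
#' @param path a file written by [write_session_report()].
#' @return a `cat_session`-equivalent list: `steps`, `responses`, `final`,
#'   `stop_reason`, `outfit`, `aberrant`, `scale`.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keys <- read_key_lines(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  st <- utils::read.csv(text = paste(body, collapse = "\n"))
  st$unexpected <- as.logical(st$unexpected)
  scale <- rating_scale(num_or_na(strsplit(keys[["thresholds"]], ",")[[1L]]))
  final <- ability_estimate(as.numeric(keys[["final_theta"]]),
                            as.numeric(keys[["final_se"]]), nrow(st))
  structure(list(steps = st,
                 responses = data.frame(item_id = st$item_id,
                                        difficulty = st$difficulty,
                                        category = st$response),
                 final = final, stop_reason = keys[["stop_reason"]],
                 outfit = as.numeric(keys[["outfit"]]),
                 aberrant = as.logical(keys[["aberrant"]]),
                 scale = scale),
            class = "cat_session")
}
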