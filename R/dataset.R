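#' Behavioral datasets
#'
#' A behavioral dataset is a data.frame with one row per trial and columns
#' `subject`, `phase` (`learning`/`transfer`/`estimation`), `trial`,
#' `context`, `stim_left`, `stim_right`, `choice`, `r_chosen`, `r_unchosen`,
#' `confidence`, `estimate`.  Stimuli are labelled `A1`, `B`, `A2`, `C`;
#' missing responses are `NA` (empty fields on disk).  The feedback regime
#' and, for synthetic data, the generating-model metadata travel as
#' attributes (`regime`, `meta`).
#'
#' `validate_dataset()` checks the structural invariants: learning-phase
#' length within the configured bounds (unless the run is flagged excluded),
#' exactly `6 * transfer_repeats` transfer rows and
#' `4 * estimation_repeats` estimation rows per subject, and `r_unchosen`
#' present on answered learning trials if and only if the regime is
#' complete.
#'
#' @param data a behavioral data.frame.
#' @param regime `"partial"` or `"complete"`; defaults to the `regime`
#'   attribute.
#' @param config an [task_config()] used for the length invariants.
#' @return `validate_dataset()` returns `data` invisibly, or stops with an
#'   informative error.
#' @export
validate_dataset <- function(data, regime = attr(data, "regime"),
                             config = task_config(regime = regime)) {
  cols <- c("subject", "phase", "trial", "context", "stim_left",
            "stim_right", "choice", "r_chosen", "r_unchosen",
            "confidence", "estimate")
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("dataset schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (is.null(regime)) stop("dataset has no feedback regime")
  bad <- setdiff(unique(data$phase), c("learning", "transfer", "estimation"))
  if (length(bad)) stop("unknown phase value(s): ", paste(bad, collapse = ", "))
  meta <- attr(data, "meta")
  for (sj in unique(data$subject)) {
    d <- data[data$subject == sj, ]
    nl <- sum(d$phase == "learning")
    excl <- isTRUE(meta[[as.character(sj)]]$excluded)
    if (!excl && (nl < config$min_trials || nl > config$max_trials))
      stop("subject ", sj, ": learning-phase length ", nl,
           " outside [", config$min_trials, ", ", config$max_trials, "]")
    nt <- sum(d$phase == "transfer")
    if (nt != 6L * config$transfer_repeats)
      stop("subject ", sj, ": expected ", 6L * config$transfer_repeats,
           " transfer rows, found ", nt)
    ne <- sum(d$phase == "estimation")
    if (ne != 4L * config$estimation_repeats)
      stop("subject ", sj, ": expected ", 4L * config$estimation_repeats,
           " estimation rows, found ", ne)
    lrn <- d[d$phase == "learning" & !is.na(d$choice), ]
    if (regime == "complete" && anyNA(lrn$r_unchosen))
      stop("subject ", sj, ": complete-feedback learning trials lack r_unchosen")
    if (regime == "partial" && any(!is.na(lrn$r_unchosen)))
      stop("subject ", sj, ": partial-feedback learning trials carry r_unchosen")
  }
  invisible(data)
}

#' Write / read a behavioral dataset as CSV
#'
#' UTF-8 comma-separated text with header row
#' `subject,phase,trial,context,stim_left,stim_right,choice,r_chosen,r_unchosen,confidence,estimate`.
#' Missing values are empty fields.  The feedback regime and any
#' generating-model metadata are stored in `#`-prefixed comment lines above
#' the header, so the round trip is lossless.
#'
#' @param data a behavioral dataset (see [validate_dataset()]).
#' @param path file path.
#' @return `read_dataset()` returns the dataset with its `regime` and `meta`
#'   attributes restored.
#' @examples
#' \donttest{
#' cfg <- task_config()
#' d <- simulate_agent("OL1", c(beta = 0.05, alpha1 = 0.3), cfg, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_dataset(d, f)
#' d2 <- read_dataset(f)
#' all.equal(d, d2, check.attributes = FALSE)
#' }
#' @export
write_dataset <- function(data, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#regime: ", attr(data, "regime")), con)
  meta <- attr(data, "meta")
  if (!is.null(meta)) {
    # single-line YAML payload; newlines escaped so the header stays line-based
    y <- yaml::as.yaml(meta, line.sep = "\n", precision = 15)
    writeLines(paste0("#meta: ", gsub("\n", "\\\\n", sub("\n$", "", y))), con)
  }
  write.csv(data, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  regime <- NULL; meta <- NULL
  for (h in hdr) {
    if (startsWith(lines[h], "#regime: "))
      regime <- sub("^#regime: ", "", lines[h])
    if (startsWith(lines[h], "#meta: "))
      meta <- yaml::yaml.load(gsub("\\\\n", "\n",
                                   sub("^#meta: ", "", lines[h])))
  }
  if (is.null(regime) || !regime %in% c("partial", "complete"))
    stop("unknown or missing feedback regime in ", path)
  body <- lines[setdiff(seq_along(lines), hdr)]
  data <- tryCatch(
    read.csv(text = body, stringsAsFactors = FALSE,
             colClasses = c(subject = "character", phase = "character",
                            trial = "integer", context = "character",
                            stim_left = "character", stim_right = "character",
                            choice = "character", r_chosen = "numeric",
                            r_unchosen = "numeric", confidence = "numeric",
                            estimate = "numeric"),
             na.strings = ""),
    error = function(e) stop("malformed dataset rows in ", path, ": ",
                             conditionMessage(e)))
  nfield <- nchar(gsub("[^,]", "", body[-1])) + 1L
  badrows <- which(nfield != 11L & nzchar(body[-1]))
  if (length(badrows))
    stop("malformed dataset row(s) at line ",
         paste(badrows + 1L + length(hdr), collapse = ", "), " in ", path)
  if (regime == "complete" && all(is.na(data$r_unchosen[data$phase == "learning"])))
    stop("dataset schema error: complete-regime file has no r_unchosen values")
  attr(data, "regime") <- regime
  attr(data, "meta") <- meta
  data
}

# learning-phase rows with an answered choice, coded as index vectors for
# the likelihood core; `left`/`right` retained for residual/diagnostic use
.coded_learning <- function(data, subject = NULL) {
  d <- data[data$phase == "learning", ]
  if (!is.null(subject)) d <- d[d$subject == subject, ]
  d <- d[!is.na(d$choice), ]
  if (!nrow(d)) return(NULL)
  ch <- .stim_index(d$choice)
  lf <- .stim_index(d$stim_left); rt <- .stim_index(d$stim_right)
  un <- ifelse(ch == lf, rt, lf)
  if (any(ch != lf & ch != rt))
    stop("choice is not one of the displayed stimuli")
  list(chosen = ch, unchosen = un, context = .CONTEXT_OF[ch],
       tidx = as.integer(d$trial), r_ch = d$r_chosen, r_un = d$r_unchosen,
       n = nrow(d))
}

.coded_transfer <- function(data, subject = NULL) {
  d <- data[data$phase == "transfer", ]
  if (!is.null(subject)) d <- d[d$subject == subject, ]
  d <- d[!is.na(d$choice), ]
  if (!nrow(d)) return(NULL)
  ch <- .stim_index(d$choice)
  lf <- .stim_index(d$stim_left); rt <- .stim_index(d$stim_right)
  un <- ifelse(ch == lf, rt, lf)
  list(chosen = ch, unchosen = un, n = nrow(d))
}
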