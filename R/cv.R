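# Cross-validation schemes: a single stratified 60/40 holdout and
# leave-one-group-out with the participant as the group, which prevents
# segments of one subject from straddling train and test.

#' Define a cross-validation scheme
#'
#' @param kind `"holdout_60_40"` (one stratified fold, 60% train / 40% test)
#'   or `"leave_one_group_out"` (one fold per participant, that
#'   participant's segments as the test set).
#' @param seed Integer seed for the holdout draw.
#' @param train_fraction Training fraction for the holdout scheme.
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(kind = c("holdout_60_40", "leave_one_group_out"),
                      seed = 1L, train_fraction = 0.6) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed),
                 train_fraction = train_fraction),
            class = "cv_scheme")
}

#' Split a feature table into train/test folds
#'
#' Holdout: one fold, drawn per class so label proportions are preserved to
#' within one row. Leave-one-group-out: one fold per distinct
#' `participant_id`; no participant ever appears on both sides of a fold.
#'
#' @param table Feature data frame with `label` (and, for LOGO,
#'   `participant_id`) columns.
#' @param scheme A [cv_scheme()].
#' @return List of folds, each `list(train = row indices, test = row
#'   indices)`.
#' @export
cv_split <- function(table, scheme) {
  stopifnot(inherits(scheme, "cv_scheme"))
  n <- nrow(table)
  if (scheme$kind == "holdout_60_40") {
    train <- with_seed(scheme$seed, {
      unlist(lapply(split(seq_len(n), table$label), function(idx) {
        sample(idx, round(scheme$train_fraction * length(idx)))
      }), use.names = FALSE)
    })
    train <- sort(train)
    return(list(list(train = train, test = setdiff(seq_len(n), train))))
  }
  groups <- unique(table$participant_id)
  if (length(groups) < 2L) {
    stopf("leave-one-group-out needs >= 2 participants")
  }
  lapply(groups, function(g) {
    test <- which(table$participant_id == g)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
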