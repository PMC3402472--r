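#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so generators are deterministic without clobbering the
#' session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Accumulate configuration problems and raise them all at once, each naming
# the offending field.
check_collect <- function() {
  errs <- character(0)
  list(
    fail = function(msg) errs <<- c(errs, msg),
    check = function(ok, msg) if (!isTRUE(all(ok))) errs <<- c(errs, msg),
    raise = function(context) {
      if (length(errs)) {
        stop(sprintf("%s: %s", context, paste(errs, collapse = "; ")),
             call. = FALSE)
      }
      invisible(TRUE)
    }
  )
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Model channel names
#'
#' The four event channels modulated by interventions: first-ever ischaemic
#' heart disease events, ischaemic and haemorrhagic first strokes, and
#' gastrointestinal bleeds (an aspirin side-effect).
#'
#' @return character vector of channel names.
#' @export
cvd_channels <- function() c("ihd", "stroke_isch", "stroke_haem", "gi_bleed")

# Coerce an effect expressed as (ihd, stroke) or partially-named channel
# vector into the canonical four-channel relative-risk vector. An
# unqualified "stroke" RR applies to both stroke subtypes; unspecified
# channels default to 1 (no effect).
as_channel_rr <- function(x) {
  ch <- cvd_channels()
  if (is.null(names(x))) {
    if (length(x) == 1) x <- stats::setNames(rep(x, 4), ch)
    else if (length(x) == 2) x <- c(ihd = x[[1]], stroke = x[[2]])
    else if (length(x) == 4) names(x) <- ch
    else stopf("relative-risk vector must be named or of length 1, 2 or 4")
  }
  out <- stats::setNames(rep(1, 4), ch)
  for (nm in names(x)) {
    if (nm == "stroke") {
      out["stroke_isch"] <- out["stroke_isch"] * x[[nm]]
      out["stroke_haem"] <- out["stroke_haem"] * x[[nm]]
    } else if (nm %in% ch) {
      out[nm] <- x[[nm]]
    } else {
      stopf("unknown relative-risk channel '%s'", nm)
    }
  }
  if (any(out <= 0)) stopf("relative risks must be > 0")
  out
}
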