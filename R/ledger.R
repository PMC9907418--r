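GENESIS_DIGEST <- strrep("0", 64)

sha256hex <- function(x) {
  if (is.character(x)) x <- charToRaw(enc2utf8(x))
  digest::digest(x, algo = "sha256", serialize = FALSE)
}

## Canonical serialization an event digest covers: the six fields joined by
## newlines, UTF-8. Fixed bit-exactly so independent implementations agree.
eventCanonical <- function(index, timestamp, actor, action, payload_digest,
                           prev_digest) {
  paste(index, timestamp, actor, action, payload_digest, prev_digest,
        sep = "\n")
}

#' Create an empty activity ledger
#'
#' @return A [LedgerChain-class] with no events.
#' @export
ledgerChain <- function() {
  new("LedgerChain", events = data.frame(
    index = integer(), timestamp = character(), actor = character(),
    action = character(), payload_digest = character(),
    prev_digest = character(), digest = character(),
    stringsAsFactors = FALSE))
}

#' Append an activity event to a ledger
#'
#' Records one platform activity (upload, annotate, export or reward) as a
#' hash-chained event. The payload is stored only as its SHA-256 digest;
#' the event digest covers the canonical serialization of
#' index, timestamp, actor, action, payload digest and the previous event's
#' digest (newline-joined, UTF-8, lowercase hex). The first event links
#' back to 64 zero hex characters.
#'
#' @param chain a [LedgerChain-class].
#' @param actor who performed the activity.
#' @param action one of \code{"upload"}, \code{"annotate"}, \code{"export"},
#'   \code{"reward"}.
#' @param payload event payload, character or raw.
#' @param timestamp UTC ISO-8601 text; defaults to the current time.
#' @return The extended chain.
#' @examples
#' ch <- ledgerAppend(ledgerChain(), "alice", "upload", "study-1",
#'                    timestamp = "2024-01-01T00:00:00Z")
#' ledgerVerify(ch)
#' @export
ledgerAppend <- function(chain, actor, action, payload,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                            tz = "UTC")) {
  stopifnot(is(chain, "LedgerChain"))
  if (!(length(action) == 1L && action %in% LEDGER_ACTIONS))
    stop("unknown ledger action '", paste(action, collapse = ","),
         "'; permitted: ", paste(LEDGER_ACTIONS, collapse = ", "),
         call. = FALSE)
  if (length(actor) != 1L || !nzchar(actor))
    stop("actor must be a single non-empty string", call. = FALSE)
  ev <- chain@events
  index <- nrow(ev)
  prev <- if (index == 0L) GENESIS_DIGEST else ev$digest[index]
  pd <- sha256hex(payload)
  dg <- sha256hex(eventCanonical(index, timestamp, actor, action, pd, prev))
  chain@events <- rbind(ev, data.frame(
    index = as.integer(index), timestamp = as.character(timestamp),
    actor = as.character(actor), action = as.character(action),
    payload_digest = pd, prev_digest = prev, digest = dg,
    stringsAsFactors = FALSE))
  chain
}

#' Verify the integrity of a ledger chain
#'
#' Recomputes every event digest from the stored fields and checks every
#' back-link and the index sequence. Verification is a pure function of the
#' chain contents and never throws.
#'
#' @param chain a [LedgerChain-class].
#' @return List with \code{ok} (logical) and \code{firstBadIndex} (the
#'   index of the first failing event, or NA when the chain is intact).
#' @export
ledgerVerify <- function(chain) {
  ev <- tryCatch(chain@events, error = function(e) NULL)
  if (is.null(ev)) return(list(ok = FALSE, firstBadIndex = 0L))
  if (nrow(ev) == 0L) return(list(ok = TRUE, firstBadIndex = NA_integer_))
  for (n in seq_len(nrow(ev))) {
    e <- ev[n, ]
    expectPrev <- if (n == 1L) GENESIS_DIGEST else ev$digest[n - 1L]
    bad <- !identical(as.integer(e$index), n - 1L) ||
      !identical(e$prev_digest, expectPrev) ||
      !(e$action %in% LEDGER_ACTIONS) ||
      !identical(e$digest,
                 sha256hex(eventCanonical(n - 1L, e$timestamp, e$actor,
                                          e$action, e$payload_digest,
                                          e$prev_digest)))
    if (bad) return(list(ok = FALSE, firstBadIndex = n - 1L))
  }
  list(ok = TRUE, firstBadIndex = NA_integer_)
}

#' Read and write the ledger file format
#'
#' Line-oriented flat file: one event per line, the seven fields
#' (index, timestamp, actor, action, payload_digest, prev_digest, digest)
#' joined by tab characters, UTF-8, no header. [readLedger()] performs no
#' verification; call [ledgerVerify()] on the result.
#'
#' @param chain a [LedgerChain-class].
#' @param path file path.
#' @return \code{writeLedger}: \code{path}, invisibly. \code{readLedger}:
#'   a [LedgerChain-class].
#' @export
writeLedger <- function(chain, path) {
  stopifnot(is(chain, "LedgerChain"))
  ev <- chain@events
  lines <- sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s", ev$index, ev$timestamp,
                   ev$actor, ev$action, ev$payload_digest, ev$prev_digest,
                   ev$digest)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeLedger
#' @export
readLedger <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) return(ledgerChain())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 7L))
    stop("malformed ledger line ", which(lengths(parts) != 7L)[1L],
         call. = FALSE)
  m <- do.call(rbind, parts)
  new("LedgerChain", events = data.frame(
    index = as.integer(m[, 1L]), timestamp = m[, 2L], actor = m[, 3L],
    action = m[, 4L], payload_digest = m[, 5L], prev_digest = m[, 6L],
    digest = m[, 7L], stringsAsFactors = FALSE))
}
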