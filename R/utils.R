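#' @keywords internal
"_PACKAGE"

## Classed conditions ---------------------------------------------------

agent_abort <- function(message, class, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "agent_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

validation_error <- function(message, ...) {
  agent_abort(message, "agent_validation_error", ...)
}

parse_error <- function(message, ...) {
  agent_abort(message, "agent_parse_error", ...)
}

config_error <- function(message, ...) {
  agent_abort(message, "agent_config_error", ...)
}

contract_error <- function(message, ...) {
  agent_abort(message, "agent_contract_error", ...)
}

io_error <- function(message, ...) {
  agent_abort(message, "agent_io_error", ...)
}

infra_error <- function(message, ...) {
  agent_abort(message, "agent_infra_error", ...)
}

## Scalar checks ---------------------------------------------------------

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_nonempty_string <- function(x) is_string(x) && nzchar(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == trunc(x)
}

## FNV-1a 32-bit hash ----------------------------------------------------
##
## Self-contained so transcript matcher keys are portable across platforms.
## Multiplication is done on 16-bit halves to stay within double precision.

fnv1a32 <- function(x) {
  stopifnot(is_string(x))
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  p <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor64(h, b)
    hl <- h %% two16
    hh <- (h - hl) / two16
    h <- (hl * p + ((hh * p) %% two16) * two16) %% two32
  }
  # h can exceed .Machine$integer.max; format in 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# bitwXor works on 32-bit signed ints; route through a safe split for
# values >= 2^31.
bitwXor64 <- function(a, b) {
  two31 <- 2147483648
  hi <- 0
  if (a >= two31) {
    a <- a - two31
    hi <- 1
  }
  r <- bitwXor(as.integer(a), as.integer(b))
  if (r < 0) r <- r + 4294967296  # defensive; operands are < 2^31
  r + hi * two31
}

## Deterministic pseudo-random sequences ---------------------------------
##
## Linear congruential generator with documented constants
## (a = 1664525, c = 1013904223, m = 2^32), kept independent of R's RNG so
## fixture payload bytes are reproducible across implementations.

lcg_new <- function(seed) {
  stopifnot(is_count(seed))
  env <- new.env(parent = emptyenv())
  env$state <- seed %% 4294967296
  env
}

lcg_next <- function(gen) {
  a <- 1664525
  c <- 1013904223
  two16 <- 65536
  two32 <- 4294967296
  s <- gen$state
  sl <- s %% two16
  sh <- (s - sl) / two16
  s <- (sl * a + ((sh * a) %% two16) * two16 + c) %% two32
  gen$state <- s
  s
}

# integer in [0, n)
lcg_int <- function(gen, n) {
  floor(lcg_next(gen) / 4294967296 * n)
}

lcg_chars <- function(gen, n, alphabet) {
  idx <- vapply(seq_len(n), function(i) lcg_int(gen, length(alphabet)) + 1L, 1)
  paste(alphabet[idx], collapse = "")
}

## JSON-lines run log ----------------------------------------------------

log_open <- function(path) {
  env <- new.env(parent = emptyenv())
  env$path <- path
  if (!file.exists(path)) file.create(path)
  env
}

log_event <- function(log, event, payload = list()) {
  if (is.null(log)) return(invisible(NULL))
  rec <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
              event = event, payload = payload)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  cat(line, "\n", sep = "", file = log$path, append = TRUE)
  invisible(NULL)
}

read_log_events <- function(path) {
  if (!file.exists(path)) io_error(sprintf("run log not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
}

## Misc ------------------------------------------------------------------

tail_chars <- function(x, n) {
  if (!is_string(x) || nchar(x) <= n) return(x)
  substr(x, nchar(x) - n + 1L, nchar(x))
}

# collapse all whitespace runs to single spaces and trim
normalize_ws <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}
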