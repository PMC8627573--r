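# All permutations of a vector, as rows (used to exercise order invariance
# of the step-down adjustment).
perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], perms(v[-i]), deparse.level = 0)))
}
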