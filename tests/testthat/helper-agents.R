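# trained agents are expensive; cache them across test files
agent_cache <- new.env(parent = emptyenv())

cached_agent <- function(group, seed = 1L, ...) {
  key <- paste(group, seed, ...)
  if (is.null(agent_cache[[key]])) {
    agent_cache[[key]] <- train_agent(tom_config(group = group, seed = seed,
                                                 ...))
  }
  agent_cache[[key]]
}
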