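{
  "cycles": {
    "b": [
      ["rxns{C-38a740ac8bce53c6f635d5611e269ab3,C-f50c1b82c83ab28e248ada04e1037e9b}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-38a740ac8bce53c6f635d5611e269ab3,M-af63df4c8601f1a527a410b23259f856=C-f50c1b82c83ab28e248ada04e1037e9b}"]
    ]
  },
  "multiple_products": {
    "t": [
      ["rxns{C-87ff61bf96dc5d8866f0d614d04212e5,C-d65c9335f0ca11c29e2e875f7ebe57e7}|prov{M-af63e94c860202a327a402b23259e08c=C-d65c9335f0ca11c29e2e875f7ebe57e7,M-af63ec4c860207bc27a3ffb23259db73=C-87ff61bf96dc5d8866f0d614d04212e5,M-af63ed4c8602096f27a3feb23259d9c0=C-87ff61bf96dc5d8866f0d614d04212e5}"]
    ]
  },
  "common_intermediates": {
    "t": [
      ["rxns{C-84de0dafcc37ef643b0f951af6968c89,C-a32b8392002ee8a425b3ca168b83d049,C-a32b8692002eedbd25b3c7168b83cb30}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-a32b8692002eedbd25b3c7168b83cb30,M-af63df4c8601f1a527a410b23259f856=C-a32b8392002ee8a425b3ca168b83d049,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"]
    ]
  },
  "branch_in_cycle": {
    "c": [
      ["rxns{C-3342425b3f5b277165c9bfdc8de8e8e2,C-599a591518e016ccbaad51d0e16bea4f,C-f50c1b82c83ab28e248ada04e1037e9b}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-3342425b3f5b277165c9bfdc8de8e8e2,M-af63de4c8601eff227a411b23259fa09=C-599a591518e016ccbaad51d0e16bea4f,M-af63df4c8601f1a527a410b23259f856=C-f50c1b82c83ab28e248ada04e1037e9b}"]
    ]
  },
  "concurrent_branching": {
    "t": [
      ["rxns{C-30655749936796c268a6aeee39dc805d,C-3342425b3f5b277165c9bfdc8de8e8e2,C-84de0dafcc37ef643b0f951af6968c89}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-3342425b3f5b277165c9bfdc8de8e8e2,M-af63df4c8601f1a527a410b23259f856=C-30655749936796c268a6aeee39dc805d,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"],
      ["rxns{C-30655749936796c268a6aeee39dc805d,C-84de0dafcc37ef643b0f951af6968c89,C-c305245273151bb6d607dde55a30a79d}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-c305245273151bb6d607dde55a30a79d,M-af63df4c8601f1a527a410b23259f856=C-30655749936796c268a6aeee39dc805d,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"],
      ["rxns{C-3342425b3f5b277165c9bfdc8de8e8e2,C-752aab85017da7b5222f5ab2ca568dea,C-84de0dafcc37ef643b0f951af6968c89}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-3342425b3f5b277165c9bfdc8de8e8e2,M-af63df4c8601f1a527a410b23259f856=C-752aab85017da7b5222f5ab2ca568dea,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"],
      ["rxns{C-3342425b3f5b277165c9bfdc8de8e8e2,C-84de0dafcc37ef643b0f951af6968c89,C-e28ad77c21d016dcb4ce26bbaa025e2b}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-3342425b3f5b277165c9bfdc8de8e8e2,M-af63df4c8601f1a527a410b23259f856=C-e28ad77c21d016dcb4ce26bbaa025e2b,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"],
      ["rxns{C-752aab85017da7b5222f5ab2ca568dea,C-84de0dafcc37ef643b0f951af6968c89,C-c305245273151bb6d607dde55a30a79d}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-c305245273151bb6d607dde55a30a79d,M-af63df4c8601f1a527a410b23259f856=C-752aab85017da7b5222f5ab2ca568dea,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"],
      ["rxns{C-84de0dafcc37ef643b0f951af6968c89,C-c305245273151bb6d607dde55a30a79d,C-e28ad77c21d016dcb4ce26bbaa025e2b}|prov{M-af63dc4c8601ec8c27a40fb23259f6a3=C-c305245273151bb6d607dde55a30a79d,M-af63df4c8601f1a527a410b23259f856=C-e28ad77c21d016dcb4ce26bbaa025e2b,M-af63e94c860202a327a402b23259e08c=C-84de0dafcc37ef643b0f951af6968c89}"]
    ]
  }
}
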