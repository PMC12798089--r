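{
  "T": [
    ["rxns{C-19e0e46b71c5118afe615331c4e8b09f,C-2c4a9fdfc68921ddb086d06453512ba0,C-2efdac8b54d9c77542005c1e3bf5425e,C-7fdeefd09007b8efada9b052a75d40e2,C-9f3b7b942120fff3d1c309156faedc94,C-e237dab9eb43f8a8fe2c4046851a6cf5,C-e9f2ec8e8abde404fce900e227136ea9}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af63f94c86021dd327a432b2325a321c=C-2efdac8b54d9c77542005c1e3bf5425e,M-af63fc4c860222ec27a42fb2325a2d03=C-e237dab9eb43f8a8fe2c4046851a6cf5,M-af63ff4c8602280527a430b2325a2eb6=C-19e0e46b71c5118afe615331c4e8b09f,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-9f3b7b942120fff3d1c309156faedc94,M-af64094c8602390327a422b2325a16ec=C-e9f2ec8e8abde404fce900e227136ea9}"],
    ["rxns{C-19e0e46b71c5118afe615331c4e8b09f,C-2c4a9fdfc68921ddb086d06453512ba0,C-2efdac8b54d9c77542005c1e3bf5425e,C-7fdeefd09007b8efada9b052a75d40e2,C-c89da17c0fbe65973560728db4ea974e,C-e237dab9eb43f8a8fe2c4046851a6cf5,C-e9f2ec8e8abde404fce900e227136ea9}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af63f94c86021dd327a432b2325a321c=C-2efdac8b54d9c77542005c1e3bf5425e,M-af63fc4c860222ec27a42fb2325a2d03=C-e237dab9eb43f8a8fe2c4046851a6cf5,M-af63ff4c8602280527a430b2325a2eb6=C-19e0e46b71c5118afe615331c4e8b09f,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-c89da17c0fbe65973560728db4ea974e,M-af64094c8602390327a422b2325a16ec=C-e9f2ec8e8abde404fce900e227136ea9}"],
    ["rxns{C-19e0e46b71c5118afe615331c4e8b09f,C-2c4a9fdfc68921ddb086d06453512ba0,C-7fdeefd09007b8efada9b052a75d40e2,C-9f3b7b942120fff3d1c309156faedc94,C-9f3b839421210d8bd1c301156faecefc,C-cdb9679e019f2b3dfb84282018f4b330,C-e9f2ec8e8abde404fce900e227136ea9}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af63fc4c860222ec27a42fb2325a2d03=C-cdb9679e019f2b3dfb84282018f4b330,M-af63fe4c8602265227a431b2325a3069=C-9f3b839421210d8bd1c301156faecefc,M-af63ff4c8602280527a430b2325a2eb6=C-19e0e46b71c5118afe615331c4e8b09f,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-9f3b7b942120fff3d1c309156faedc94,M-af64094c8602390327a422b2325a16ec=C-e9f2ec8e8abde404fce900e227136ea9}"],
    ["rxns{C-19e0e46b71c5118afe615331c4e8b09f,C-2c4a9fdfc68921ddb086d06453512ba0,C-7fdeefd09007b8efada9b052a75d40e2,C-9f3b839421210d8bd1c301156faecefc,C-c89da17c0fbe65973560728db4ea974e,C-cdb9679e019f2b3dfb84282018f4b330,C-e9f2ec8e8abde404fce900e227136ea9}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af63fc4c860222ec27a42fb2325a2d03=C-cdb9679e019f2b3dfb84282018f4b330,M-af63fe4c8602265227a431b2325a3069=C-9f3b839421210d8bd1c301156faecefc,M-af63ff4c8602280527a430b2325a2eb6=C-19e0e46b71c5118afe615331c4e8b09f,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-c89da17c0fbe65973560728db4ea974e,M-af64094c8602390327a422b2325a16ec=C-e9f2ec8e8abde404fce900e227136ea9}"],
    ["rxns{C-1c060e69d498ae5a2387b51cbc014c13,C-2efda98b54d9c25c42005b1e3bf540ab,C-2efdac8b54d9c77542005c1e3bf5425e,C-9f3b839421210d8bd1c301156faecefc,C-cdb9679e019f2b3dfb84282018f4b330,C-e237dab9eb43f8a8fe2c4046851a6cf5,C-e9f2ec8e8abde404fce900e227136ea9}|prov{M-af63f94c86021dd327a432b2325a321c=C-2efdac8b54d9c77542005c1e3bf5425e,M-af63fa4c86021f8627a435b2325a3735=C-2efda98b54d9c25c42005b1e3bf540ab,M-af63fc4c860222ec27a42fb2325a2d03=C-cdb9679e019f2b3dfb84282018f4b330,M-af63fe4c8602265227a431b2325a3069=C-9f3b839421210d8bd1c301156faecefc,M-af63ff4c8602280527a430b2325a2eb6=C-1c060e69d498ae5a2387b51cbc014c13,M-af64054c8602323727a436b2325a38e8=C-e237dab9eb43f8a8fe2c4046851a6cf5,M-af64094c8602390327a422b2325a16ec=C-e9f2ec8e8abde404fce900e227136ea9}"],
    ["rxns{C-1c060e69d498ae5a2387b51cbc014c13,C-2efda98b54d9c25c42005b1e3bf540ab,C-2efdac8b54d9c77542005c1e3bf5425e,C-e237dab9eb43f8a8fe2c4046851a6cf5,C-e9f2ec8e8abde404fce900e227136ea9}|prov{M-af63f94c86021dd327a432b2325a321c=C-2efdac8b54d9c77542005c1e3bf5425e,M-af63fa4c86021f8627a435b2325a3735=C-2efda98b54d9c25c42005b1e3bf540ab,M-af63fc4c860222ec27a42fb2325a2d03=C-e237dab9eb43f8a8fe2c4046851a6cf5,M-af63ff4c8602280527a430b2325a2eb6=C-1c060e69d498ae5a2387b51cbc014c13,M-af64054c8602323727a436b2325a38e8=C-e237dab9eb43f8a8fe2c4046851a6cf5,M-af64094c8602390327a422b2325a16ec=C-e9f2ec8e8abde404fce900e227136ea9}"]
  ],
  "B": [
    ["rxns{C-19e0e46b71c5118afe615331c4e8b09f,C-2c4a9fdfc68921ddb086d06453512ba0,C-7fdeefd09007b8efada9b052a75d40e2,C-9f3b7b942120fff3d1c309156faedc94}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af63ff4c8602280527a430b2325a2eb6=C-19e0e46b71c5118afe615331c4e8b09f,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-9f3b7b942120fff3d1c309156faedc94}"],
    ["rxns{C-19e0e46b71c5118afe615331c4e8b09f,C-2c4a9fdfc68921ddb086d06453512ba0,C-7fdeefd09007b8efada9b052a75d40e2,C-c89da17c0fbe65973560728db4ea974e}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af63ff4c8602280527a430b2325a2eb6=C-19e0e46b71c5118afe615331c4e8b09f,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-c89da17c0fbe65973560728db4ea974e}"],
    ["rxns{C-1c060e69d498ae5a2387b51cbc014c13,C-2efda98b54d9c25c42005b1e3bf540ab,C-2efdac8b54d9c77542005c1e3bf5425e,C-e237dab9eb43f8a8fe2c4046851a6cf5}|prov{M-af63f94c86021dd327a432b2325a321c=C-2efdac8b54d9c77542005c1e3bf5425e,M-af63fa4c86021f8627a435b2325a3735=C-2efda98b54d9c25c42005b1e3bf540ab,M-af63ff4c8602280527a430b2325a2eb6=C-1c060e69d498ae5a2387b51cbc014c13,M-af64054c8602323727a436b2325a38e8=C-e237dab9eb43f8a8fe2c4046851a6cf5}"]
  ],
  "E": [
    ["rxns{C-2c4a9fdfc68921ddb086d06453512ba0,C-7fdeefd09007b8efada9b052a75d40e2,C-9f3b7b942120fff3d1c309156faedc94}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-9f3b7b942120fff3d1c309156faedc94}"],
    ["rxns{C-2c4a9fdfc68921ddb086d06453512ba0,C-7fdeefd09007b8efada9b052a75d40e2,C-c89da17c0fbe65973560728db4ea974e}|prov{M-af63f84c86021c2027a433b2325a33cf=C-7fdeefd09007b8efada9b052a75d40e2,M-af64044c8602308427a437b2325a3a9b=C-2c4a9fdfc68921ddb086d06453512ba0,M-af64064c860233ea27a439b2325a3e01=C-c89da17c0fbe65973560728db4ea974e}"]
  ]
}
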