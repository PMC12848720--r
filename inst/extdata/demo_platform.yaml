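# Small two-vessel rig for the quench-or-transfer demonstration: a
# reactor holding 5 mL of orange reaction mixture, an empty holding
# flask, and a blue quenching-stock flask, all on one valve.
vessels:
- id: reactor_1
  capacity: 100.0
  temperature: 20.0
  pH: 7.0
  contents:
  - solution: orange
    volume: 5.0
- id: holding_flask
  capacity: 100.0
  temperature: 20.0
  pH: 7.0
stocks:
- color: blue
  id: stock_blue
  volume: 100.0
nodes:
- pump_1
- valve_1
edges:
- - pump_1
  - valve_1
- - reactor_1
  - valve_1
- - holding_flask
  - valve_1
- - stock_blue
  - valve_1
- - waste
  - valve_1
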