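vessels:
- id: tape_1
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_1
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_2
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_2
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_3
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_3
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_4
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_4
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_5
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_5
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_6
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_6
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_7
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_7
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: tape_8
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: head_8
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: state_1
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: state_2
  capacity: 10.0
  temperature: 20.0
  pH: 7.0
- id: waste
  capacity: Inf
  temperature: 20.0
  pH: 7.0
solutions:
- id: orange
  color: orange
- id: blue
  color: blue
- id: green
  color: green
stocks:
- color: orange
  id: stock_orange
  volume: 1000.0
- color: blue
  id: stock_blue
  volume: 1000.0
- color: green
  id: stock_green
  volume: 1000.0
nodes:
- pump_1
- pump_2
- pump_3
- valve_1
- valve_2
- valve_3
- valve_4
- valve_5
edges:
- - valve_1
  - valve_2
- - valve_2
  - valve_3
- - valve_3
  - valve_4
- - valve_4
  - valve_5
- - pump_1
  - valve_1
- - pump_2
  - valve_3
- - pump_3
  - valve_5
- - tape_1
  - valve_2
- - head_1
  - valve_4
- - tape_2
  - valve_1
- - head_2
  - valve_3
- - tape_3
  - valve_2
- - head_3
  - valve_4
- - tape_4
  - valve_1
- - head_4
  - valve_3
- - tape_5
  - valve_2
- - head_5
  - valve_4
- - tape_6
  - valve_1
- - head_6
  - valve_3
- - tape_7
  - valve_2
- - head_7
  - valve_4
- - tape_8
  - valve_1
- - head_8
  - valve_3
- - state_1
  - valve_5
- - state_2
  - valve_5
- - stock_orange
  - valve_5
- - stock_blue
  - valve_5
- - stock_green
  - valve_5
- - waste
  - valve_5
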