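<XDL>
  <Reagents>
    <Reagent id="quencher" color="blue"/>
  </Reagents>
  <Vessels>
    <Vessel id="reactor_1"/>
    <Vessel id="holding_flask"/>
  </Vessels>
  <Procedure>
    <Measure step_id="C" vessel="reactor_1" quantity="color" comparison="equal" value="orange"/>
    <Add vessel="reactor_1" reagent="quencher" volume="2" condition="C"/>
    <Transfer from_vessel="reactor_1" to_vessel="holding_flask" volume="5" condition="not C"/>
  </Procedure>
</XDL>
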